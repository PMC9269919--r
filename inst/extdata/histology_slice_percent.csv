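animal,group,slice,percent_fibrosis
dog_1,experimental,2,32.43
dog_1,experimental,3,23.43
dog_1,experimental,5,13.09
dog_1,experimental,6,12.77
dog_1,experimental,7,19.17
dog_2,experimental,1,29.51
dog_2,experimental,2,23.38
dog_2,experimental,3,25.63
dog_2,experimental,4,19.35
dog_2,experimental,5,18.53
dog_2,experimental,6,17.36
dog_2,experimental,7,14.83
dog_3,experimental,4,22.17
dog_3,experimental,5,19.37
dog_5,experimental,6,14.28
dog_5,experimental,7,33.18
dog_6,experimental,2,8.99
dog_6,experimental,3,12.87
dog_6,experimental,4,8.74
dog_6,experimental,5,11.69
dog_6,experimental,6,13.57
control_3,control,1,3.06
control_3,control,2,2.55
control_3,control,3,2.24
control_3,control,4,0.34
control_3,control,5,1.08
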