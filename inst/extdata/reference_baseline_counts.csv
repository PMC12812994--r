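drug,drug_total,group,category,count,printed_pct
bortezomib,33322,sex,Female,10386,31.2
bortezomib,33322,sex,Male,13409,40.2
bortezomib,33322,sex,Missing,9527,28.6
carfilzomib,14063,sex,Female,4768,33.9
carfilzomib,14063,sex,Male,6010,42.7
carfilzomib,14063,sex,Missing,3285,23.4
ixazomib,16562,sex,Female,7514,45.4
ixazomib,16562,sex,Male,8256,49.8
ixazomib,16562,sex,Missing,792,4.8
bortezomib,33322,age,<18,993,3.0
bortezomib,33322,age,18-64.9,8229,24.7
bortezomib,33322,age,65-85,9575,28.7
bortezomib,33322,age,>85,382,1.1
bortezomib,33322,age,Missing,14143,42.4
carfilzomib,14063,age,<18,138,1.0
carfilzomib,14063,age,18-64.9,4055,28.8
carfilzomib,14063,age,65-85,4937,35.1
carfilzomib,14063,age,>85,127,0.9
carfilzomib,14063,age,Missing,4806,34.2
ixazomib,16562,age,<18,414,2.5
ixazomib,16562,age,18-64.9,2538,15.3
ixazomib,16562,age,65-85,5978,36.1
ixazomib,16562,age,>85,545,3.3
ixazomib,16562,age,Missing,7087,42.8
bortezomib,33322,outcome,Death,4137,12.4
bortezomib,33322,outcome,Disability,173,0.5
bortezomib,33322,outcome,Hospitalization,5076,15.2
bortezomib,33322,outcome,Life-threatening,694,2.1
bortezomib,33322,outcome,Other,23241,69.7
carfilzomib,14063,outcome,Death,2466,17.5
carfilzomib,14063,outcome,Disability,87,0.6
carfilzomib,14063,outcome,Hospitalization,3360,23.9
carfilzomib,14063,outcome,Life-threatening,684,4.9
carfilzomib,14063,outcome,Other,7466,53.1
ixazomib,16562,outcome,Death,3627,21.9
ixazomib,16562,outcome,Disability,37,0.2
ixazomib,16562,outcome,Hospitalization,4492,27.1
ixazomib,16562,outcome,Life-threatening,180,1.1
ixazomib,16562,outcome,Other,8226,49.7
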