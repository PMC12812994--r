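drug,drug_total,pt,count,printed_pct
bortezomib,9013,Neuropathy peripheral,2681,29.7
bortezomib,9013,Polyneuropathy,393,4.4
bortezomib,9013,Neurotoxicity,221,2.4
bortezomib,9013,Peripheral sensory neuropathy,171,1.9
bortezomib,9013,Neuralgia,117,1.3
bortezomib,9013,Autonomic neuropathy,96,1.1
bortezomib,9013,Posterior reversible encephalopathy syndrome,87,1.0
bortezomib,9013,Guillain-Barre syndrome,72,0.8
bortezomib,9013,Peripheral motor neuropathy,53,0.6
bortezomib,9013,Peripheral sensorimotor neuropathy,45,0.5
carfilzomib,2119,Neuropathy peripheral,248,11.7
carfilzomib,2119,Polyneuropathy,58,2.7
carfilzomib,2119,Posterior reversible encephalopathy syndrome,53,2.5
carfilzomib,2119,Encephalopathy,43,2.0
carfilzomib,2119,Hypertensive encephalopathy,7,0.3
carfilzomib,2119,Intracranial mass,5,0.2
carfilzomib,2119,Autonomic neuropathy,4,0.2
carfilzomib,2119,Cauda equina syndrome,4,0.2
carfilzomib,2119,Central nervous system haemorrhage,3,0.1
carfilzomib,2119,Cerebral small vessel ischaemic disease,3,0.1
ixazomib,3450,Neuropathy peripheral,675,19.6
ixazomib,3450,Paraesthesia,252,7.3
ixazomib,3450,Dementia,74,2.1
ixazomib,3450,Neurological symptom,31,0.9
ixazomib,3450,Ataxia,31,0.9
ixazomib,3450,Myoclonus,30,0.9
ixazomib,3450,Peripheral sensory neuropathy,17,0.5
ixazomib,3450,Chorea,16,0.5
ixazomib,3450,Post herpetic neuralgia,6,0.2
ixazomib,3450,Autonomic neuropathy,5,0.1
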