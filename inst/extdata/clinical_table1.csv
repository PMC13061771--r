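Sample GEO accession,Baseline seizure frequency (Seizure/month),Gender,Age,Epilepsy duration,Onset age,Etiology
GSM6725527,1,M,26,4,22,Unk
GSM6725534,60,M,19,7,12,TBI
GSM6725528,0.33,F,32,8,24,CVA
GSM6725532,4,F,45,8,37,Abor
GSM6725529,4,M,16,10,6,Unk
GSM6725530,1,F,35,13,22,Unk
GSM6725524,3,M,38,17,21,Unk
GSM6725537,1,M,26,19,7,Unk
GSM6725536,2,M,32,25,7,Unk
GSM6725525,0.25,M,37,35,2,Unk
GSM6725531,1,F,54,36,18,Ecl
GSM6725538,4,M,45,37,8,Unk
GSM6725539,2,F,58,37,21,Unk
GSM6725533,2,M,46,43,3,Unk
GSM6725526,0.25,M,60,47,13,Unk
GSM6725535,2,F,62,61,1,Inf
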