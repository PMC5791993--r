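state,abbrev,nsdp_pc,nsdp_rank,hlc_mean,hlc_rank,hlc_sd
Jammu and Kashmir,JM,22.406,20,0.813,11,1.073
Himachal Pradesh,HP,35.806,6,0.992,6,0.794
Punjab,PJ,34.096,9,1.240,4,0.926
Uttaranchal,UC,27.781,13,0.833,10,1.041
Haryana,HR,40.627,4,0.804,12,0.966
Delhi,DL,69.128,2,1.845,1,0.814
Rajasthan,RJ,19.445,21,0.224,19,1.154
Uttar Pradesh,UP,13.445,28,-0.044,25,1.082
Bihar,BH,7.588,29,-0.484,29,0.846
Sikkim,SK,29.008,12,0.925,8,0.916
Arunachal Pradesh,AR,26.870,15,0.311,18,1.062
Nagaland,NA,33.072,10,0.419,16,0.935
Manipur,MN,19.341,22,0.646,15,0.900
Mizoram,MZ,25.826,16,1.213,5,0.957
Tripura,TR,25.688,17,0.113,21,0.885
Meghalaya,MG,24.278,18,0.135,20,1.039
Assam,AS,17.050,26,-0.126,26,1.101
West Bengal,WB,23.808,19,0.055,23,1.057
Jharkhand,JH,17.406,25,-0.311,28,1.048
Orissa,OR,18.194,24,-0.155,27,0.938
Chhattisgarh,CH,18.530,23,-0.007,24,0.973
Madhya Pradesh,MP,15.927,27,0.095,22,1.054
Gujarat,GJ,36.102,5,0.922,9,1.005
Maharashtra,MH,40.671,3,0.932,7,1.070
Andhra Pradesh,AP,27.179,14,0.348,17,0.861
Karnataka,KA,29.295,11,0.667,14,0.972
Goa,GO,80.844,1,1.456,2,1.049
Kerala,KE,35.492,7,1.253,3,0.834
Tamil Nadu,TN,34.126,8,0.735,13,0.918
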