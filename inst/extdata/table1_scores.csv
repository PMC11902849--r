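subject_id,age,sex,diagnosis,days_since_onset,hemiplegic_side,session,arat,mbi,fmue
1,42,M,Left pontine infarction,28,right,baseline,30,77,44
2,63,F,"Right basal ganglia, thalamic hemorrhage",148,left,baseline,14,44,29
3,65,M,"Left corona radiata, basal ganglia infarction",185,right,baseline,46,80,56
4,69,M,"Left corona radiata, basal ganglia infarction",17,right,baseline,12,17,16
5,45,M,Left PCA infarction,344,right,baseline,49,63,52
6,52,F,Right thalamic infarction,16,left,baseline,51,83,53
7,56,F,Right MCA infarction,86,left,baseline,52,86,56
8,71,F,Left thalamic hemorrhage,25,right,baseline,13,20,4
9,89,M,Left middle cerebral artery territory infarction,26,right,baseline,22,16,31
1,42,M,Left pontine infarction,28,right,followup,53,93,55
2,63,F,"Right basal ganglia, thalamic hemorrhage",148,left,followup,18,48,38
5,45,M,Left PCA infarction,344,right,followup,55,66,62
6,52,F,Right thalamic infarction,16,left,followup,55,92,62
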