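scenario,sex,smoking_status,deaths
baseline,male,current,5537917
baseline,male,former,3572169
baseline,male,never,146933
baseline,female,current,1603169
baseline,female,former,773426
baseline,female,never,3351513
cms,male,current,5121750
cms,male,former,3379508
cms,male,never,146933
cms,female,current,1516785
cms,female,former,747049
cms,female,never,3351513
cng,male,current,5064225
cng,male,former,3462941
cng,male,never,146933
cng,female,current,1467832
cng,female,former,749120
cng,female,never,3351513
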