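item,question,prevalence
somatic symptoms,1,0.054900
somatic symptoms,2,0.013983
somatic symptoms,3,0.046025
somatic symptoms,4,0.089164
fatigue,1,0.031361
fatigue,2,0.010973
fatigue,3,0.041452
fatigue,4,0.035758
concentration,1,0.099854
concentration,2,0.013065
concentration,3,0.033808
concentration,4,0.012636
sleep,1,0.040964
sleep,2,0.030253
sleep,3,0.109343
sleep,4,0.040740
irritability,1,0.293828
irritability,2,0.011138
irritability,3,0.213827
irritability,4,0.041564
worry about physical health,1,0.025368
worry about physical health,2,0.015803
worry about physical health,3,0.133898
worry about physical health,4,0.061938
depression,1,0.160773
depression,2,0.046724
depression,3,0.068970
depression,4,0.016287
depressive ideas,1,0.071064
depressive ideas,2,0.248133
depressive ideas,3,0.242122
depressive ideas,4,0.151050
depressive ideas,5,0.057985
worry,1,0.119612
worry,2,0.296632
worry,3,0.040898
worry,4,0.075850
anxiety,1,0.047721
anxiety,2,0.104380
anxiety,3,0.010399
anxiety,4,0.194352
phobias,1,0.279228
phobias,2,0.010147
phobias,3,0.029033
phobias,4,0.085980
panic,1,0.080463
panic,2,0.144838
panic,3,0.052206
panic,4,0.032676
compulsions,1,0.140917
compulsions,2,0.014958
compulsions,3,0.019051
compulsions,4,0.015709
obsessions,1,0.101953
obsessions,2,0.041157
obsessions,3,0.294045
obsessions,4,0.209526
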