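condition,rate,family,sd,a,b,n,seed,skewness,modal_score,fit_range,slope,intercept,r_squared,n_bins_used,error
rate1_normal_sd1,1,normal,1,NA,NA,10000,1296711049,2.404640092,1,right_tail,-0.07852916049,6.233850837,0.8926887609,56,
rate1_normal_sd2,1,normal,2,NA,NA,10000,1100209856,1.904403528,8,right_tail,-0.1017974408,7.1969639,0.9690428616,47,
rate1_normal_sd3,1,normal,3,NA,NA,10000,903708663,1.548306109,11,right_tail,-0.1416875071,8.527364933,0.9832703982,40,
rate1_normal_sd4,1,normal,4,NA,NA,10000,707207470,1.236249162,16,right_tail,-0.1782349414,9.873134266,0.9832759063,32,
rate2_normal_sd1,2,normal,1,NA,NA,10000,1509104802,2.002856903,8,right_tail,-0.1033485846,7.19251886,0.9635743847,48,
rate3_normal_sd1,3,normal,1,NA,NA,10000,1721498555,1.560604708,13,right_tail,-0.1360673351,8.433209406,0.9820026355,38,
rate2_normal_sd2,2,normal,2,NA,NA,10000,1312603609,1.204611941,16,right_tail,-0.1714239488,9.722059405,0.9890615663,32,
rate3_normal_sd2,3,normal,2,NA,NA,10000,1524997362,0.7449168506,20,right_tail,-0.2330042363,11.96185465,0.9847721349,24,
rate1_uniform_0_5,1,uniform,NA,0,5,10000,1405007651,1.606273175,0,full_range,-0.08371578661,6.688374667,0.9854476916,57,
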