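team,league_points,wins,losses,ties,goals_scored_mean,goals_scored_se,goals_conceded_mean,goals_conceded_se
infants,9701,2888,75,1037,2.43,0.04,0.02,0.003
squares,7463,1898,333,1769,1.03,0.02,0.09,0.01
circles,6602,1696,790,1514,1.21,0.03,0.25,0.01
lines,2927,611,2295,1094,0.20,0.01,1.14,0.02
no-training,400,0,3600,400,0,0,3.36,0.03
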