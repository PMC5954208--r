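team,league_points,wins,losses,ties,goals_scored_mean,goals_scored_se,goals_conceded_mean,goals_conceded_se
purple,11786,3420,54,1526,1.46,0.02,0.02,0.001
red,9307,2407,507,2086,0.89,0.02,0.13,0.01
blue,8052,1982,912,2106,0.74,0.01,0.23,0.01
yellow,7561,1795,1029,2176,0.63,0.01,0.26,0.01
green,3655,912,3169,919,0.30,0.01,1.15,0.02
lines,155,0,4845,155,0,0,2.26,0.01
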