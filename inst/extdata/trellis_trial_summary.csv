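year,treatment,lateral_leaf_area,total_leaf_area,cluster_number,berry_wt,cluster_wt,vine_yield,ravaz_index
2014,shw,1.14,4.24,9.2,2.85,315,2.89,5.38
2014,vsp,1.86,3.87,10.2,2.91,268,2.63,6.47
2015,shw,1.21,3.78,10.4,2.12,287,2.67,5.86
2015,vsp,1.45,3.25,10.6,2.28,224,2.37,5.95
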