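compound_id,calc_kd_uM,recurrence,total_runs,normalized_kd_uM
R55/1,128.5,15,40,189.0
2a,1.8,35,40,0.53
3a,9.2,25,40,5.1
4a,82.1,29,40,27.5
5a,290.6,7,40,561
6a,3.8,9,40,7.1
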