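sex,age_band,ratio
female,40-44,7.0
female,45-49,6.0
female,50-54,5.0
female,55-59,4.5
female,60-64,3.5
female,65-69,2.8
female,70-74,2.0
female,75-79,1.5
female,80+,1.1
male,40-44,4.0
male,45-49,3.5
male,50-54,3.0
male,55-59,2.5
male,60-64,2.0
male,65-69,1.6
male,70-74,1.2
male,75-79,1.0
male,80+,0.8
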