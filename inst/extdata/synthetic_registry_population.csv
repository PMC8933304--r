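year,sex,nationality,age_band,count
2017,female,expatriate,40-44,7500
2017,female,expatriate,45-49,6000
2017,female,expatriate,50-54,4500
2017,female,expatriate,55-59,3000
2017,female,expatriate,60-64,1750
2017,female,expatriate,65-69,875
2017,female,expatriate,70-74,375
2017,female,expatriate,75-79,175
2017,female,expatriate,80+,125
2017,female,national,40-44,2362
2017,female,national,45-49,2100
2017,female,national,50-54,1838
2017,female,national,55-59,1444
2017,female,national,60-64,1050
2017,female,national,65-69,656
2017,female,national,70-74,394
2017,female,national,75-79,236
2017,female,national,80+,184
2017,male,expatriate,40-44,15000
2017,male,expatriate,45-49,12000
2017,male,expatriate,50-54,9000
2017,male,expatriate,55-59,6000
2017,male,expatriate,60-64,3500
2017,male,expatriate,65-69,1750
2017,male,expatriate,70-74,750
2017,male,expatriate,75-79,300
2017,male,expatriate,80+,200
2017,male,national,40-44,2250
2017,male,national,45-49,2000
2017,male,national,50-54,1750
2017,male,national,55-59,1375
2017,male,national,60-64,1000
2017,male,national,65-69,625
2017,male,national,70-74,375
2017,male,national,75-79,225
2017,male,national,80+,175
2018,female,expatriate,40-44,7500
2018,female,expatriate,45-49,6000
2018,female,expatriate,50-54,4500
2018,female,expatriate,55-59,3000
2018,female,expatriate,60-64,1750
2018,female,expatriate,65-69,875
2018,female,expatriate,70-74,375
2018,female,expatriate,75-79,175
2018,female,expatriate,80+,125
2018,female,national,40-44,2362
2018,female,national,45-49,2100
2018,female,national,50-54,1838
2018,female,national,55-59,1444
2018,female,national,60-64,1050
2018,female,national,65-69,656
2018,female,national,70-74,394
2018,female,national,75-79,236
2018,female,national,80+,184
2018,male,expatriate,40-44,15000
2018,male,expatriate,45-49,12000
2018,male,expatriate,50-54,9000
2018,male,expatriate,55-59,6000
2018,male,expatriate,60-64,3500
2018,male,expatriate,65-69,1750
2018,male,expatriate,70-74,750
2018,male,expatriate,75-79,300
2018,male,expatriate,80+,200
2018,male,national,40-44,2250
2018,male,national,45-49,2000
2018,male,national,50-54,1750
2018,male,national,55-59,1375
2018,male,national,60-64,1000
2018,male,national,65-69,625
2018,male,national,70-74,375
2018,male,national,75-79,225
2018,male,national,80+,175
2019,female,expatriate,40-44,7500
2019,female,expatriate,45-49,6000
2019,female,expatriate,50-54,4500
2019,female,expatriate,55-59,3000
2019,female,expatriate,60-64,1750
2019,female,expatriate,65-69,875
2019,female,expatriate,70-74,375
2019,female,expatriate,75-79,175
2019,female,expatriate,80+,125
2019,female,national,40-44,2362
2019,female,national,45-49,2100
2019,female,national,50-54,1838
2019,female,national,55-59,1444
2019,female,national,60-64,1050
2019,female,national,65-69,656
2019,female,national,70-74,394
2019,female,national,75-79,236
2019,female,national,80+,184
2019,male,expatriate,40-44,15000
2019,male,expatriate,45-49,12000
2019,male,expatriate,50-54,9000
2019,male,expatriate,55-59,6000
2019,male,expatriate,60-64,3500
2019,male,expatriate,65-69,1750
2019,male,expatriate,70-74,750
2019,male,expatriate,75-79,300
2019,male,expatriate,80+,200
2019,male,national,40-44,2250
2019,male,national,45-49,2000
2019,male,national,50-54,1750
2019,male,national,55-59,1375
2019,male,national,60-64,1000
2019,male,national,65-69,625
2019,male,national,70-74,375
2019,male,national,75-79,225
2019,male,national,80+,175
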