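month,total_reviews,positive_hygiene,negative_hygiene
2023-01-01,50,4,5
2023-02-01,40,7,4
2023-03-01,60,6,6
2023-04-01,45,8,4
2023-05-01,55,5,5
2023-06-01,30,3,15
2023-07-01,50,4,5
2023-08-01,40,3,4
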