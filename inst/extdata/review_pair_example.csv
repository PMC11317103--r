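review,text
1,"It was my first time to taste this dish and totally satisfied. I cut down that 5th star because it lacks spice and realized that there are spicy sauces that can be added to the dish, after our plates were empty. Good ambience and service."
2,"Whoever people looking for delicious food and humble service at the place of absolute sizzler only i can say that I had good experience there especially i heard about that discount on ala carte menu and on the buffet 50off that was really cool and great dine to have, at that reasonable price number of buffet items which were making us feel tasty thanks to absolute Sizzlers ...."
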