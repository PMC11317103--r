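category,n_negative,n_positive,CLEANLINESS_DINING,EXTERNAL_OBJECTS,FOOD_HANDLING,FOOD_PACKAGING,PEST_CONTROL,UNDERCOOKED_ROTTEN_SMELLY,UNINTENDED_HEALTH_OUTCOME,UPKEEP_INFRA
BUFFET,6,2,3,0,1,0,0,2,0,0
CASUAL_DINING,6,4,0,0,1,0,0,5,0,0
QUICK_SERVICE,3,1,0,1,0,1,0,0,0,1
FOOD_TRUCK_DHABA,6,3,1,0,0,0,0,5,0,0
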