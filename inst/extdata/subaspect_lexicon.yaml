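# Default sub-aspect lexicon: eight food-safety sub-aspects derived from the
# Indian regulatory inspection checklist (plus the added unintended-health-
# outcome category). Each entry lists exemplar complaint phrases and short
# single-word triggers; matching is lowercase, punctuation-free and
# stem-prefix based ("rats" matches trigger "rat").
CLEANLINESS_DINING:
  - unclean tables
  - dirty floors
  - dirty
  - unclean
EXTERNAL_OBJECTS:
  - stone in the rice
  - hair in the curry
  - stone
  - hair
FOOD_HANDLING:
  - dipped hands in drinks
  - the waiter looked unhealthy
  - bare hands
  - sneezed on the food
FOOD_PACKAGING:
  - wrapped food in old newspaper
  - the container was leaking
  - leaking
  - broken seal
PEST_CONTROL:
  - saw a rat in the washroom
  - found a fly in the soup
  - rat
  - fly
  - cockroach
UNDERCOOKED_ROTTEN_SMELLY:
  - chicken was undercooked
  - cheese was smelly
  - bread had fungus developed
  - undercooked
  - stale
  - smelly
  - fungus
  - rotten
UNINTENDED_HEALTH_OUTCOME:
  - vomited after eating mayonnaise
  - had stomach ache due to biryani
  - vomit
  - acidity
  - stomach ache
  - loose motion
  - food poisoning
UPKEEP_INFRA:
  - poorly ventilated
  - ac not working
  - ventilated
  - damp
  - walls were peeling
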