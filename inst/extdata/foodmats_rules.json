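{
  "version": "1.0",
  "comment": "Editable default classification rules. Product rules are ordered; the first pattern (case-insensitive regex on 'name category_hint') that matches decides the class. Energy-dense keywords are listed before whole-food keywords so that e.g. 'fruit punch' resolves before 'fruit'.",
  "product_rules": [
    {"pattern": "fruit punch|fruit drink|fruit snack", "class": "least_healthy"},
    {"pattern": "milkshake|milk shake", "class": "least_healthy"},
    {"pattern": "soft drink|\\bcola\\b|\\bsoda\\b|\\bpop\\b", "class": "least_healthy"},
    {"pattern": "sports drink|energy drink|slush|iced cap", "class": "least_healthy"},
    {"pattern": "candy|chocolate|gum\\b|licorice", "class": "least_healthy"},
    {"pattern": "chips|fries|poutine|nachos|onion ring", "class": "least_healthy"},
    {"pattern": "ice cream|sundae|frozen dessert|blizzard", "class": "least_healthy"},
    {"pattern": "hot dog|pizza|burger|fried chicken|corn dog", "class": "least_healthy"},
    {"pattern": "donut|doughnut|cookie|cake|brownie|pastry", "class": "least_healthy"},
    {"pattern": "\\bwater\\b", "class": "most_healthy"},
    {"pattern": "vegetable|salad|carrot|celery", "class": "most_healthy"},
    {"pattern": "\\bfruit\\b|apple|banana|orange(?! soda)|berries", "class": "most_healthy"},
    {"pattern": "plain milk|white milk|\\bmilk\\b(?! chocolate)", "class": "most_healthy"},
    {"pattern": "\\begg\\b|plain yogurt|smoothie", "class": "most_healthy"},
    {"pattern": "granola|muffin|cereal bar|trail mix", "class": "less_healthy"},
    {"pattern": "juice|chocolate milk", "class": "less_healthy"},
    {"pattern": "coffee|\\btea\\b|latte", "class": "less_healthy"},
    {"pattern": "sandwich|wrap\\b|sub\\b|bagel", "class": "less_healthy"},
    {"pattern": "yogurt|cheese|crackers|popcorn|pretzel|soup", "class": "less_healthy"}
  ],
  "retailer_rules": {
    "grocery_store": "most_healthy",
    "farmers_market": "most_healthy",
    "salad_bar": "most_healthy",
    "sandwich_outlet": "most_healthy",
    "smoothie_outlet": "most_healthy",
    "sit_down_restaurant": "less_healthy",
    "cafeteria": "less_healthy",
    "coffee_outlet": "less_healthy",
    "prepared_grocery": "less_healthy",
    "supplement_store": "less_healthy",
    "pizza_outlet": "least_healthy",
    "burger_outlet": "least_healthy",
    "taco_outlet": "least_healthy",
    "fried_chicken_outlet": "least_healthy",
    "asian_outlet": "least_healthy",
    "ice_cream_outlet": "least_healthy",
    "pub_lounge_alcohol": "least_healthy"
  },
  "brand_map": {
    "Coca-Cola": "sweetened soft drink",
    "Pepsi": "sweetened soft drink",
    "Sprite": "sweetened soft drink",
    "Aquafina": "bottled water",
    "Dasani": "bottled water",
    "Gatorade": "sports drink",
    "Powerade": "sports drink",
    "Red Bull": "energy drink",
    "Tropicana": "orange juice",
    "Frito-Lay": "potato chips",
    "Doritos": "tortilla chips",
    "Hershey": "chocolate bar",
    "Nestle": "chocolate bar",
    "Dairyland": "white milk",
    "Minute Maid": "juice"
  },
  "technique_vocab": {
    "child": [
      "cartoon_character", "fictional_character", "animated_character",
      "taste_appeal", "humour", "action_adventure", "fantasy",
      "fun_shapes_colours", "competition", "give_away",
      "cartoonish_font", "child_actor"
    ],
    "sports": [
      "physical_activity_reference", "exercise_reference",
      "sport_reference", "game_reference", "recreation_reference",
      "performance_reference", "competition_reference"
    ]
  },
  "pricing_indicators": [
    {"indicator_id": 1, "group": "overeating_rewards", "label": "combo/meal deal encourages larger purchase"},
    {"indicator_id": 2, "group": "overeating_rewards", "label": "volume discount on unhealthy item"},
    {"indicator_id": 3, "group": "overeating_rewards", "label": "loyalty/repeat-visit reward"},
    {"indicator_id": 4, "group": "overeating_rewards", "label": "free refill on sweetened beverage"},
    {"indicator_id": 5, "group": "price_comparison", "label": "sweetened drink cheaper than water"},
    {"indicator_id": 6, "group": "price_comparison", "label": "sweetened drink cheaper than plain milk"},
    {"indicator_id": 7, "group": "price_comparison", "label": "candy/chocolate cheaper than fruit"},
    {"indicator_id": 8, "group": "price_comparison", "label": "chips cheaper than healthier snack"},
    {"indicator_id": 9, "group": "price_comparison", "label": "fried entree cheaper than non-fried entree"},
    {"indicator_id": 10, "group": "price_comparison", "label": "largest drink size cheapest per unit"},
    {"indicator_id": 11, "group": "price_comparison", "label": "dessert cheaper than fruit/yogurt option"}
  ]
}
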