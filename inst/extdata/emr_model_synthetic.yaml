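# Reference instance of the 18-category Eastern Mediterranean nutrient-profile
# taxonomy, with beverage subcategories 3a-3e and the two extension categories
# (alcoholic drinks, coffee) seen in broadcast corpora but outside the model.
#
# SYNTHETIC THRESHOLDS: the category list, subcategories and auto-not-permitted
# flags follow the regional model; the numeric threshold values below are
# plausible placeholders for testing and demonstration only. For regulatory
# work, replace them with the officially published limits (same schema).
#
# Thresholds are maxima per 100 g (solids) or per 100 mL (liquids); a product
# exceeding any applicable threshold is not permitted for marketing to
# children. Absent keys mean the nutrient is not applicable to the category.
categories:
  - category_id: "1"
    name: "Chocolate and sugar confectionery, energy bars, sweet toppings and desserts"
    auto_not_permitted: true
  - category_id: "2"
    name: "Savoury snacks"
    thresholds: {total_fat_g: 10, total_sugars_g: 10, salt_g: 0.1}
  - category_id: "3a"
    name: "Fruit juices"
    auto_not_permitted: true
  - category_id: "3b"
    name: "Vegetable juices"
    thresholds: {total_sugars_g: 5, added_sugars_g: 0, salt_g: 0.5}
  - category_id: "3c"
    name: "Milk drinks"
    sweeteners_prohibited: true
    thresholds: {total_fat_g: 2.5, total_sugars_g: 10, added_sugars_g: 0}
  - category_id: "3d"
    name: "Energy drinks"
    auto_not_permitted: true
  - category_id: "3e"
    name: "Other beverages"
    sweeteners_prohibited: true
    thresholds: {energy_kcal: 4, added_sugars_g: 0}
  - category_id: "4"
    name: "Edible ices"
    auto_not_permitted: true
  - category_id: "5"
    name: "Breakfast cereals"
    thresholds: {total_fat_g: 10, total_sugars_g: 15, salt_g: 1.6}
  - category_id: "6"
    name: "Cakes, sweet biscuits and pastries; other sweet baked goods and dry mixes"
    auto_not_permitted: true
  - category_id: "7"
    name: "Yoghurts, sour milk, cream and similar foods"
    sweeteners_prohibited: true
    thresholds: {total_fat_g: 2.5, saturated_fat_g: 2, total_sugars_g: 10, salt_g: 0.2}
  - category_id: "8"
    name: "Ready-made and convenience foods and composite dishes"
    thresholds: {energy_kcal: 225, total_fat_g: 10, saturated_fat_g: 4, total_sugars_g: 10, salt_g: 1}
  - category_id: "9"
    name: "Cheeses"
    thresholds: {total_fat_g: 20, salt_g: 1.3}
  - category_id: "10"
    name: "Butter and other fats and oils"
    thresholds: {saturated_fat_g: 20, salt_g: 1.3}
  - category_id: "11"
    name: "Bread, bread products and crispbreads"
    thresholds: {total_fat_g: 10, total_sugars_g: 10, salt_g: 1.2}
  - category_id: "12"
    name: "Fresh, dried or cooked pasta, rice and grains"
    thresholds: {total_fat_g: 10, total_sugars_g: 10, salt_g: 1.2}
  - category_id: "13"
    name: "Fresh and frozen meat, poultry, fish and similar"
    thresholds: {}
  - category_id: "14"
    name: "Processed meat, poultry and similar"
    auto_not_permitted: true
  - category_id: "15"
    name: "Processed fish and similar"
    thresholds: {total_fat_g: 20, salt_g: 1.7}
  - category_id: "16"
    name: "Fresh and frozen fruit, vegetables and legumes"
    thresholds: {}
  - category_id: "17"
    name: "Processed fruit, vegetables and legumes"
    thresholds: {total_fat_g: 5, added_sugars_g: 0, salt_g: 1}
  - category_id: "18"
    name: "Sauces, dips and dressings"
    thresholds: {total_fat_g: 10, total_sugars_g: 10, salt_g: 1}
  - category_id: "19"
    name: "Alcoholic drinks"
    is_model_category: false
  - category_id: "20"
    name: "Coffee"
    is_model_category: false
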