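keyword,tags
apple,fruit
banana,fruit
orange,fruit
pear,fruit
melon,fruit
fruit,fruit
carrots,vegetable
peas,vegetable
broccoli,vegetable
sweetcorn,vegetable
vegetables,vegetable
salad,salad
coleslaw,salad
fish,fish
cod,fish
haddock,fish
salmon,fish;oily_fish
mackerel,fish;oily_fish
sardines,fish;oily_fish
tuna,fish
beef,red_meat;meat_cut
lamb,red_meat;meat_cut
pork,red_meat;meat_cut
mince,red_meat
bacon,processed_meat;red_meat
sausage,processed_meat;red_meat
ham,processed_meat;red_meat
pepperoni,processed_meat;red_meat
chicken popcorn,processed_meat
nuggets,processed_meat
chicken,poultry
turkey,poultry;meat_cut
roast chicken,poultry;meat_cut
lentil,non_meat_protein
chickpea,non_meat_protein
beans,non_meat_protein
egg,non_meat_protein
quorn,non_meat_protein
tofu,non_meat_protein;vegan_alternative
jackfruit,non_meat_protein;vegan_alternative
vegan,vegan_alternative
soya milk,non_dairy_milk;vegan_alternative
oat milk,non_dairy_milk;vegan_alternative
potato,potato
potatoes,potato
chips,potato
wedges,potato
pasta,non_potato_starch
rice,non_potato_starch
noodles,non_potato_starch
couscous,non_potato_starch
bread,bread
baguette,bread
roll,bread
sandwich,bread
panini,bread
toast,bread
wrap,bread
wholemeal,wholegrain
wholegrain,wholegrain
porridge,wholegrain
oats,wholegrain
milk,milk
semi-skimmed milk,milk;lower_fat_milk
skimmed milk,milk;lower_fat_milk
yogurt,yogurt
low-sugar yogurt,yogurt;low_sugar_yogurt
chocolate,hfss_confectionery
sweets,hfss_confectionery
crisps,hfss_savoury
cookie,hfss_sweet_snack
biscuit,hfss_sweet_snack
flapjack,hfss_sweet_snack
muffin,hfss_sweet_snack
traybake,hfss_sweet_snack
cake,hfss_sweet_snack
oatcakes,compliant_snack
breadsticks,compliant_snack
cheese and biscuits,compliant_snack
fruit pot,fruit;compliant_snack
water,drink
juice,drink
squash,drink
milkshake,drink
sugar-free,sugar_info_present
no added sugar,sugar_info_present
500ml,sugar_info_present
330ml,sugar_info_present
salt sachet,salt_sachet
salt,salt_sachet
ketchup,condiment
low-fat spread,condiment
spread,condiment
butter,condiment
meal of the day,meal_of_day
meal deal,meal_deal
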