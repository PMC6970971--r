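food_name,food_ingredients,fat_100g,energy_100g,carbohydrate_100g,category
coffee,coffee beans;water,0.0,2,0.0,other
tea,tea leaves;water,0.0,1,0.3,other
burger,beef;bun;lettuce;tomato,14.0,295,24.0,other
pizza,dough;tomato;cheese,10.1,266,33.0,other
noodles,wheat;egg,2.1,138,25.0,other
cake,flour;sugar;butter;egg,15.0,347,50.0,other
pie,flour;butter;fruit filling,12.5,265,38.0,other
juice,fruit,0.1,45,10.4,juice
fruits,fruit,0.3,60,14.0,fruit
veggies,vegetables,0.2,35,7.0,vegetable
fries,potato;oil;salt,15.0,312,41.0,other
poutine,fries;cheese curds;gravy,11.0,197,22.0,other
apple,apple,0.2,52,14.0,fruit
banana,banana,0.3,89,23.0,fruit
orange juice,orange;water,0.2,45,10.0,juice
sweet potato,sweet potato,0.1,86,20.0,vegetable
chicken masala,chicken;tomato;cream;spices,9.0,195,6.0,other
penne arrabiata,pasta;tomato;chili;garlic,4.0,148,24.0,other
bacon,pork belly;salt,42.0,541,1.4,other
milk,milk,3.3,61,4.8,other
cookie,flour;sugar;butter;chocolate,24.0,488,64.0,other
chocolate,cocoa;sugar;milk,31.0,546,61.0,other
cheese,milk;rennet;salt,33.0,402,1.3,other
bread,flour;water;yeast,3.2,265,49.0,other
butter,cream;salt,81.0,717,0.1,other
eggs,egg,11.0,155,1.1,other
potato,potato,0.1,77,17.0,vegetable
salad,lettuce;tomato;cucumber;dressing,7.0,102,5.0,vegetable
sandwich,bread;ham;cheese;lettuce,9.0,250,28.0,other
soup,broth;vegetables,1.5,56,8.0,other
pasta,wheat;water,1.1,158,31.0,other
rice,rice;water,0.3,130,28.0,other
sushi,rice;fish;seaweed,0.7,145,30.0,other
taco,tortilla;beef;cheese;salsa,12.0,226,20.0,other
donut,flour;sugar;oil,25.0,452,51.0,other
muffin,flour;sugar;blueberry,16.0,377,54.0,other
bagel,flour;water;yeast,1.7,250,49.0,other
steak,beef,19.0,271,0.0,other
salmon,salmon,13.0,208,0.0,other
vegan burger,soy;pea protein;bun,9.0,177,15.0,other
ice cream,cream;sugar;milk,11.0,207,24.0,other
hot dog,sausage;bun;mustard,18.0,290,18.0,other
smoothie,fruit;yogurt;ice,1.0,80,17.0,juice
yogurt,milk;cultures,3.3,59,4.7,other
cereal,grains;sugar,2.7,379,84.0,other
pancake,flour;egg;milk,9.0,227,28.0,other
waffle,flour;egg;butter;milk,14.0,291,33.0,other
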