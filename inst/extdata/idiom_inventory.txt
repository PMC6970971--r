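# Gold-standard multiword-expression inventory (fixture).
# One phrase per line; optional tab-separated tag: idiom | compound.
piece of cake	idiom
apple of my eye	idiom
apple of my eyes	idiom
smart cookie	idiom
one smart cookie	idiom
tough cookie	idiom
bring home the bacon	idiom
crying over spilled milk	idiom
cry over spilled milk	idiom
cup of tea	idiom
not my cup of tea	idiom
big cheese	idiom
couch potato	idiom
hot potato	idiom
spill the beans	idiom
full of beans	idiom
bad egg	idiom
good egg	idiom
nest egg	idiom
egg on your face	idiom
walk on eggshells	idiom
sell like hot cakes	idiom
take the cake	idiom
icing on the cake	idiom
cherry on top	idiom
go bananas	idiom
top banana	idiom
second banana	idiom
big fish	idiom
bigger fish to fry	idiom
cold turkey	idiom
duck soup	idiom
easy as pie	idiom
eat humble pie	idiom
piece of the pie	idiom
sour grapes	idiom
grain of salt	idiom
salt of the earth	idiom
worth your salt	idiom
two peas in a pod	idiom
bread and butter	idiom
butter fingers	idiom
carrot and stick	idiom
chew the fat	idiom
cream of the crop	idiom
cut the mustard	idiom
go nuts	idiom
half baked	idiom
in a pickle	idiom
in a nutshell	idiom
gravy train	idiom
hard nut to crack	idiom
tough nut to crack	idiom
nutty as a fruitcake	idiom
packed like sardines	idiom
souped up	idiom
sugar coat	idiom
spice things up	idiom
variety is the spice of life	idiom
toast of the town	idiom
upset the apple cart	idiom
use your noodle	idiom
cool as a cucumber	idiom
the way the cookie crumbles	idiom
have your cake and eat it	idiom
out to lunch	idiom
pie in the sky	idiom
cheap as chips	idiom
bun in the oven	idiom
butter someone up	idiom
cash cow	idiom
cream rises to the top	idiom
different kettle of fish	idiom
like two peas	idiom
proof is in the pudding	idiom
take with a pinch of salt	idiom
that old chestnut	idiom
whole enchilada	idiom
big enchilada	idiom
peach of a day	idiom
plum job	idiom
go pear shaped	idiom
milk it for all	idiom
butter up	idiom
sweet potato	compound
sweet potatoes	compound
ice cream	compound
hot dog	compound
french fries	compound
orange juice	compound
peanut butter	compound
olive oil	compound
green tea	compound
fried rice	compound
spring roll	compound
chicken masala	compound
penne arrabiata	compound
apple pie	compound
fruit salad	compound
energy drink	compound
sweet potato pie	compound
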