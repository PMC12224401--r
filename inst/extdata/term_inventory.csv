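term,category,match_kind,priority
verdulería,fruit_vegetable_store,both,20
frutería,fruit_vegetable_store,both,20
frutas y verduras,fruit_vegetable_store,name,20
verduras y frutas,fruit_vegetable_store,name,20
frutos del país,fruit_vegetable_store,name,20
greengrocer,fruit_vegetable_store,provider_type,10
carnicería,fresh_food_retail,both,20
pescadería,fresh_food_retail,both,20
panadería,fresh_food_retail,both,20
amasandería,fresh_food_retail,name,20
lácteos,fresh_food_retail,name,10
huevería,fresh_food_retail,name,20
bakery,fresh_food_retail,provider_type,10
butcher shop,fresh_food_retail,provider_type,10
fish market,fresh_food_retail,provider_type,10
almacén,small_food_retail,both,20
abarrotes,small_food_retail,name,20
tienda de abarrotes,small_food_retail,name,30
bodega,small_food_retail,name,20
minimarket,small_food_retail,both,20
mini market,small_food_retail,name,20
despensa,small_food_retail,name,10
provisiones,small_food_retail,name,10
grocery store,small_food_retail,provider_type,10
supermercado,supermarket,both,20
hipermercado,supermarket,name,20
supermarket,supermarket,both,10
restaurante,ready_for_consumption,both,20
restaurant,ready_for_consumption,both,10
cafetería,ready_for_consumption,both,20
café,ready_for_consumption,name,10
fuente de soda,ready_for_consumption,name,20
pizzería,ready_for_consumption,name,20
sushi,ready_for_consumption,name,10
sandwichería,ready_for_consumption,name,20
cocinería,ready_for_consumption,name,20
picada,ready_for_consumption,name,10
pollo asado,ready_for_consumption,name,20
churrasquería,ready_for_consumption,name,20
empanadas,ready_for_consumption,name,10
comida al paso,ready_for_consumption,name,20
cafe,ready_for_consumption,provider_type,10
meal takeaway,ready_for_consumption,provider_type,10
tienda de conveniencia,convenience_store,name,30
conveniencia,convenience_store,name,10
ok market,convenience_store,name,30
oxxo,convenience_store,both,30
upa,convenience_store,name,30
big john,convenience_store,name,30
convenience store,convenience_store,provider_type,10
mcdonald,fast_food_chain,name,30
burger king,fast_food_chain,name,30
kfc,fast_food_chain,name,30
subway,fast_food_chain,name,30
dominos,fast_food_chain,name,30
pizza hut,fast_food_chain,name,30
telepizza,fast_food_chain,name,30
doggis,fast_food_chain,name,30
juan maestro,fast_food_chain,name,30
fast food restaurant,fast_food_chain,provider_type,10
heladería,candy_ice_cream,both,20
confitería,candy_ice_cream,name,20
dulcería,candy_ice_cream,name,20
chocolatería,candy_ice_cream,name,20
helados,candy_ice_cream,name,10
ice cream shop,candy_ice_cream,provider_type,10
candy store,candy_ice_cream,provider_type,10
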