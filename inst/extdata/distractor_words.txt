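table
window
garden
coffee
bicycle
morning
river
market
paper
bottle
street
music
kitchen
train
mountain
letter
yellow
quiet
walking
reading
cooking
weather
library
picture
bridge
forest
station
pocket
ladder
candle
basket
mirror
carpet
engine
harbor
island
jacket
meadow
napkin
orchard
pencil
ribbon
saddle
teapot
umbrella
village
wallet
anchor
blanket
cabinet
dolphin
evening
feather
granite
hallway
journal
kettle
lantern
magnet
notebook
oatmeal
pillow
quarry
rooftop
sandal
timber
utensil
valley
whistle
airport
balloon
compass
doorway
elevator
fountain
gallery
hammock
iceberg
junction
keyboard
luggage
monument
necklace
omelette
pavement
quilt
railway
satchel
tunnel
uniform
vineyard
workshop
xylophone
yogurt
zipper
afternoon
breakfast
ceiling
daylight
envelope
furniture
glacier
horizon
ink
jungle
kiosk
lighthouse
mailbox
nursery
overpass
parkway
quayside
raincoat
skylight
telescope
underpass
veranda
waterfall
yardstick
zeppelin
avenue
boulevard
courtyard
driveway
escalator
footpath
gateway
hillside
intersection
jetty
knoll
lagoon
marina
nook
outpost
pier
quadrant
riverbank
shoreline
terrace
upland
vista
walkway
crossing
yard
zone
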