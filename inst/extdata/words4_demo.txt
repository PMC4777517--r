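ABLE
ACID
AGED
ALSO
AREA
ARMY
AWAY
BABY
BACK
BALL
BAND
BANK
BARE
BARN
BASE
BATH
BEAM
BEAN
BEAR
BEAT
BEEN
BEER
BELL
BELT
BEND
BEST
BILL
BIRD
BITE
BLUE
BOAT
BODY
BOIL
BOLD
BOLT
BOMB
BOND
BONE
BOOK
BOOM
BOOT
BORE
BORN
BOSS
BOTH
BOWL
BULK
BURN
BUSH
BUSY
CAKE
CALL
CALM
CAME
CAMP
CARD
CARE
CART
CASE
CASH
CAST
CAVE
CELL
CENT
CHAT
CHIP
CITY
CLAY
CLIP
CLUB
COAL
COAT
CODE
COIL
COIN
COLD
COME
COOK
COOL
COPE
COPY
CORD
CORE
CORN
COST
COVE
CREW
CROP
CURE
DARE
DARK
DATA
DATE
DAWN
DAYS
DEAD
DEAL
DEAN
DEAR
DEBT
DEEP
DENY
DESK
DIAL
DICE
DIET
DIRT
DISH
DOCK
DOES
DOLL
DOME
DONE
DOOR
DOSE
DOVE
DOWN
DRAW
DREW
DROP
DRUM
DUAL
DUKE
DUST
DUTY
EACH
EARN
EASE
EAST
EASY
EDGE
ELSE
EVEN
EVER
EVIL
EXIT
FACE
FACT
FADE
FAIL
FAIR
FALL
FAME
FARE
FARM
FAST
FATE
FEAR
FEED
FEEL
FEET
FELL
FELT
FILE
FILL
FILM
FIND
FINE
FIRE
FIRM
FISH
FIVE
FLAT
FLOW
FOAM
FOLD
FOLK
FOND
FOOD
FOOT
FORD
FORE
FORK
FORM
FORT
FOUR
FREE
FROM
FUEL
FULL
FUND
GAIN
GAME
GANG
GATE
GAVE
GAZE
GEAR
GENE
GIFT
GIRL
GIVE
GLAD
GOAL
GOAT
GOES
GOLD
GOLF
GONE
GOOD
GORE
GOWN
GRAB
GRAY
GREW
GRID
GRIM
GRIP
GROW
GULF
HAIR
HALF
HALL
HAND
HANG
HARD
HARE
HARM
HATE
HAVE
HAWK
HEAD
HEAL
HEAP
HEAR
HEAT
HEEL
HELD
HELL
HELP
HERB
HERD
HERE
HERO
HIDE
HIGH
HILL
HINT
HIRE
HOLD
HOLE
HOLY
HOME
HOOD
HOOK
HOPE
HORN
HOSE
HOST
HOUR
HUGE
HUNG
HUNT
HURT
IDEA
INCH
INTO
IRON
ITEM
JAIL
JOIN
JOKE
JUMP
JUNE
JURY
JUST
KEEN
KEEP
KEPT
KICK
KIND
KING
KNEE
KNEW
KNOW
LACE
LACK
LADY
LAID
LAKE
LAMB
LAMP
LAND
LANE
LAST
LATE
LAWN
LEAD
LEAF
LEAN
LEAP
LEFT
LEND
LENS
LESS
LIFE
LIFT
LIKE
LIMB
LIME
LINE
LINK
LION
LIST
LIVE
LOAD
LOAN
LOCK
LOGO
LONE
LONG
LOOK
LOOP
LORD
LOSE
LOSS
LOST
LOUD
LOVE
LUCK
LUNG
MADE
MAIL
MAIN
MAKE
MALE
MALL
MANY
MARE
MARK
MASK
MASS
MATE
MATH
MAZE
MEAL
MEAN
MEAT
MEET
MELT
MENU
MERE
MESH
MESS
MILD
MILE
MILK
MILL
MIND
MINE
MINT
MISS
MODE
MOLD
MOOD
MOON
MORE
MOST
MOVE
MUCH
MUST
MYTH
NAME
NAVY
NEAR
NEAT
NECK
NEED
NEST
NEWS
NEXT
NICE
NINE
NODE
NONE
NOON
NORM
NOSE
NOTE
OBEY
ODDS
ONCE
ONLY
OPEN
ORAL
OVEN
OVER
PACE
PACK
PAGE
PAID
PAIN
PAIR
PALE
PALM
PARK
PART
PASS
PAST
PATH
PEAK
PEAR
PEER
PICK
PIER
PILE
PINE
PINK
PIPE
PLAN
PLAY
PLOT
PLUS
POEM
POET
POLE
POLL
POND
PONY
POOL
POOR
PORE
PORK
PORT
POSE
POST
POUR
PRAY
PREY
PUMP
PURE
PUSH
RACE
RACK
RAGE
RAID
RAIL
RAIN
RANK
RARE
RATE
READ
REAL
REAR
RELY
RENT
REST
RICE
RICH
RIDE
RING
RIPE
RISE
RISK
ROAD
ROAR
ROCK
RODE
ROLE
ROLL
ROOF
ROOM
ROOT
ROPE
ROSE
RUIN
RULE
RUSH
SAFE
SAGE
SAID
SAIL
SALE
SALT
SAME
SAND
SANG
SAVE
SEAL
SEAT
SEED
SEEK
SEEM
SEEN
SELF
SELL
SEND
SENT
SHIP
SHOE
SHOP
SHOT
SHOW
SHUT
SICK
SIDE
SIGN
SILK
SING
SINK
SITE
SIZE
SKIN
SLID
SLIP
SLOW
SNAP
SNOW
SOAP
SOFT
SOIL
SOLD
SOLE
SOME
SONG
SOON
SORE
SORT
SOUL
SOUP
SOUR
SPAN
SPIN
SPOT
STAR
STAY
STEM
STEP
STIR
STOP
SUCH
SUIT
SURE
SWIM
TAIL
TAKE
TALE
TALK
TALL
TANK
TAPE
TASK
TEAM
TEAR
TELL
TEND
TENT
TERM
TEST
TEXT
THAN
THAT
THEM
THEN
THEY
THIN
THIS
TIDE
TIED
TILE
TILL
TIME
TINY
TIRE
TOLD
TOLL
TONE
TOOK
TOOL
TORE
TORN
TOUR
TOWN
TRAP
TRAY
TREE
TRIM
TRIP
TRUE
TUBE
TUNE
TURN
TWIN
TYPE
UNIT
UPON
USED
USER
VARY
VAST
VERY
VIEW
VINE
VOTE
WAGE
WAIT
WAKE
WALK
WALL
WANT
WARD
WARE
WARM
WARN
WASH
WAVE
WEAK
WEAR
WEED
WEEK
WELL
WENT
WERE
WEST
WHAT
WHEN
WHOM
WIDE
WIFE
WILD
WILL
WIND
WINE
WING
WIRE
WISE
WISH
WITH
WOKE
WOLF
WOOD
WOOL
WORD
WORE
WORK
WORM
WORN
YARD
YEAR
ZERO
ZONE
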