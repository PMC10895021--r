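A	AH0
AGAIN	AH0 G EH1 N
ALWAYS	AO1 L W EY2 Z
AN	AE1 N
AND	AH0 N D
APPLE	AE1 P AH0 L
ARE	AA1 R
ASKED	AE1 S K T
AT	AE1 T
ATE	EY1 T
BABY	B EY1 B IY0
BAD	B AE1 D
BALL	B AO1 L
BE	B IY1
BED	B EH1 D
BEEN	B IH1 N
BIG	B IH1 G
BLACK	B L AE1 K
BLUE	B L UW1
BOOK	B UH1 K
BOY	B OY1
BREAD	B R EH1 D
BROKE	B R OW1 K
BROWN	B R AW1 N
BUS	B AH1 S
BUTTER	B AH1 T ER0
CAKE	K EY1 K
CAME	K EY1 M
CAR	K AA1 R
CARRIED	K AE1 R IY0 D
CAT	K AE1 T
CHAIR	CH EH1 R
CHILDREN	CH IH1 L D R AH0 N
CLEANED	K L IY1 N D
CLOCK	K L AA1 K
CLOSED	K L OW1 Z D
COAT	K OW1 T
COLD	K OW1 L D
CUP	K AH1 P
DAY	D EY1
DINNER	D IH1 N ER0
DOG	D AO1 G
DOOR	D AO1 R
DOWN	D AW1 N
DRANK	D R AE1 NG K
DRESS	D R EH1 S
DROPPED	D R AA1 P T
EGG	EH1 G
EIGHT	EY1 T
EYES	AY1 Z
FACE	F EY1 S
FARMER	F AA1 R M ER0
FATHER	F AA1 DH ER0
FEET	F IY1 T
FELL	F EH1 L
FISH	F IH1 SH
FIVE	F AY1 V
FLOOR	F L AO1 R
FLOWER	F L AW1 ER0
FOR	F AO1 R
FORK	F AO1 R K
FOUND	F AW1 N D
FOUR	F AO1 R
FROM	F R AH1 M
GARDEN	G AA1 R D AH0 N
GAVE	G EY1 V
GIRL	G ER1 L
GOOD	G UH1 D
GREEN	G R IY1 N
HAIR	HH EH1 R
HAND	HH AE1 N D
HAT	HH AE1 T
HE	HH IY1
HEAD	HH EH1 D
HEARD	HH ER1 D
HELPED	HH EH1 L P T
HER	HH ER1
HIS	HH IH1 Z
HOME	HH OW1 M
HOT	HH AA1 T
HOUSE	HH AW1 S
I	AY1
IN	IH0 N
IS	IH1 Z
IT	IH1 T
JUMPED	JH AH1 M P T
KITCHEN	K IH1 CH AH0 N
KNIFE	N AY1 F
LIKED	L AY1 K T
LITTLE	L IH1 T AH0 L
LOST	L AO1 S T
MADE	M EY1 D
MAN	M AE1 N
MEAT	M IY1 T
MILK	M IH1 L K
MORNING	M AO1 R N IH0 NG
MOTHER	M AH1 DH ER0
NEEDED	N IY1 D IH0 D
NEVER	N EH1 V ER0
NEW	N UW1
NIGHT	N AY1 T
NINE	N AY1 N
OF	AH1 V
OFTEN	AO1 F AH0 N
OLD	OW1 L D
ON	AA1 N
ONE	W AH1 N
OPENED	OW1 P AH0 N D
ORANGE	AO1 R AH0 N JH
OUT	AW1 T
OVER	OW1 V ER0
PICKED	P IH1 K T
PICTURE	P IH1 K CH ER0
PLATE	P L EY1 T
PLAYED	P L EY1 D
PLAYING	P L EY1 IH0 NG
POCKET	P AA1 K AH0 T
RAIN	R EY1 N
RAN	R AE1 N
READ	R IY1 D
RED	R EH1 D
ROAD	R OW1 D
SALT	S AO1 L T
SAT	S AE1 T
SAW	S AO1
SCHOOL	S K UW1 L
SEVEN	S EH1 V AH0 N
SHE	SH IY1
SHOES	SH UW1 Z
SHOP	SH AA1 P
SIX	S IH1 K S
SMALL	S M AO1 L
SNOW	S N OW1
SPOON	S P UW1 N
STOOD	S T UH1 D
STREET	S T R IY1 T
STRUCK	S T R AH1 K
SUGAR	SH UH1 G ER0
SUN	S AH1 N
SUPPER	S AH1 P ER0
SWEET	S W IY1 T
TABLE	T EY1 B AH0 L
TEA	T IY1
TEN	T EH1 N
THE	DH AH0
THEIR	DH EH1 R
THEY	DH EY1
THREE	TH R IY1
TO	T UW1
TODAY	T AH0 D EY1
TOLD	T OW1 L D
TOMORROW	T AH0 M AA1 R OW2
TOOK	T UH1 K
TRAIN	T R EY1 N
TREE	T R IY1
TWELVE	T W EH1 L V
TWO	T UW1
UNDER	AH1 N D ER0
UP	AH1 P
VERY	V EH1 R IY0
WALKED	W AO1 K T
WALL	W AO1 L
WANTED	W AO1 N T IH0 D
WAS	W AA1 Z
WASHED	W AA1 SH T
WATER	W AO1 T ER0
WE	W IY1
WENT	W EH1 N T
WERE	W ER1
WHITE	W AY1 T
WINDOW	W IH1 N D OW0
WITH	W IH1 DH
WOMAN	W UH1 M AH0 N
YELLOW	Y EH1 L OW0
YESTERDAY	Y EH1 S T ER0 D EY2
YOU	Y UW1
YOUNG	Y AH1 NG
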