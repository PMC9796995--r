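;;; Small subset of the CMU Pronouncing Dictionary (ARPABET, plain-text
;;; format) covering common letter-f fluency productions plus a few
;;; non-target words for error handling.
CAT  K AE1 T
DOG  D AO1 G
FACE  F EY1 S
FAIR  F EH1 R
FAKE  F EY1 K
FAN  F AE1 N
FAR  F AA1 R
FARE  F EH1 R
FARM  F AA1 R M
FATE  F EY1 T
FEAT  F IY1 T
FEET  F IY1 T
FELLOW  F EH1 L OW0
FEN  F EH1 N
FERTILE  F ER1 T AH0 L
FIG  F IH1 G
FILE  F AY1 L
FIND  F AY1 N D
FINE  F AY1 N
FIRE  F AY1 ER0
FIRE(2)  F AY1 R
FIREFLY  F AY1 ER0 F L AY2
FISH  F IH1 SH
FIVE  F AY1 V
FLEA  F L IY1
FLEE  F L IY1
FLIP  F L IH1 P
FLOP  F L AA1 P
FLOW  F L OW1
FLY  F L AY1
FOAM  F OW1 M
FOE  F OW1
FOG  F AA1 G
FOLLOW  F AA1 L OW0
FOOD  F UW1 D
FORM  F AO1 R M
FORT  F AO1 R T
FOUR  F AO1 R
FOX  F AA1 K S
FREE  F R IY1
FRY  F R AY1
FUN  F AH1 N
HOUSE  HH AW1 S
SUN  S AH1 N
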