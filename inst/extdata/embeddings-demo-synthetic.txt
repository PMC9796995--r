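30 2
find 0.98480775 0.17364818
fire 0.95105652 0.30901699
fine 0.90630779 0.42261826
file 0.83867057 0.54463904
fish 0.64278761 0.76604444
fig 0.50000000 0.86602540
fun 0.25881905 0.96592583
fan 0.08715574 0.99619470
fox -0.76604444 0.64278761
food -0.64278761 -0.76604444
fertile 0.57357644 -0.81915204
fen -0.93969262 -0.34202014
four 0.97814760 0.20791169
five 0.87461971 0.48480962
fry -0.08715574 0.99619470
fly -0.20791169 0.97814760
flip -0.42261826 0.90630779
flop -0.54463904 0.83867057
fair -0.93969262 0.34202014
fare -0.93969262 0.34202014
free -0.34202014 -0.93969262
flea -0.20791169 -0.97814760
foam -0.00000000 -1.00000000
foe 0.10452846 -0.99452190
form 0.86602540 -0.50000000
fort 0.92718385 -0.37460659
dog -0.98480775 -0.17364818
cat 0.70710678 0.70710678
house 0.25881905 -0.96592583
sun 0.98480775 -0.17364818
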