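position,length_cm,height_cm,preserved,imputed,note
1,6.10322171674453,22.2003980542261,TRUE,FALSE,synthetic (seed 42)
2,5.22514855378792,20.5253181541102,TRUE,FALSE,synthetic (seed 42)
3,5.54310069358927,19.006289113238,TRUE,FALSE,synthetic (seed 42)
4,5.57921230291437,16.9225039889782,TRUE,FALSE,synthetic (seed 42)
5,5.44470571764055,15.9198134899965,TRUE,FALSE,synthetic (seed 42)
6,,,FALSE,FALSE,
7,5.63147026052221,13.1305193466127,TRUE,FALSE,synthetic (seed 42)
8,5.1609921592028,12.0637678270764,TRUE,FALSE,synthetic (seed 42)
9,5.59641385010632,10.7456477599911,TRUE,FALSE,synthetic (seed 42)
10,5.08435313504722,10.3950545000032,TRUE,FALSE,synthetic (seed 42)
11,5.30390786472639,9.59591869486573,TRUE,FALSE,synthetic (seed 42)
12,5.41407718077454,8.72853383698058,TRUE,FALSE,synthetic (seed 42)
13,4.74515508495999,8.21131102918126,TRUE,FALSE,synthetic (seed 42)
14,4.8865407254688,7.3334112229642,TRUE,FALSE,synthetic (seed 42)
15,4.86832753483054,6.65889060073913,TRUE,FALSE,synthetic (seed 42)
16,4.92559170883696,6.35306534753307,TRUE,FALSE,synthetic (seed 42)
17,,,FALSE,FALSE,
18,4.48107476055245,5.48505928235619,TRUE,FALSE,synthetic (seed 42)
19,4.48484678081467,4.86227834668974,TRUE,FALSE,synthetic (seed 42)
20,4.80363367389162,4.57140048870404,TRUE,FALSE,synthetic (seed 42)
21,4.61963954345224,4.17798110759603,TRUE,FALSE,synthetic (seed 42)
22,4.46996557166977,3.75928096568159,TRUE,FALSE,synthetic (seed 42)
23,4.55520407281537,3.62435092167301,TRUE,FALSE,synthetic (seed 42)
24,4.60739822445338,3.27409492397523,TRUE,FALSE,synthetic (seed 42)
25,4.60349890805737,2.97926743252314,TRUE,FALSE,synthetic (seed 42)
26,4.42944728080669,2.75114724568917,TRUE,FALSE,synthetic (seed 42)
27,4.40259593147347,2.55133037302693,TRUE,FALSE,synthetic (seed 42)
28,4.29674614305908,2.31992314430931,TRUE,FALSE,synthetic (seed 42)
29,4.36118456268581,2.00296585187357,TRUE,FALSE,synthetic (seed 42)
30,4.27997329869067,1.97122915144995,TRUE,FALSE,synthetic (seed 42)
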