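"standard","condition","rep1","rep2","rep3","rep4","rep5","rep6"
"TAG 17:0_17:0_17:0","neat",208486,214016,225208,198602,212820,210686
"TAG 17:0_17:0_17:0","unspiked",16904,14839,15543,17454,15983,17802
"TAG 17:0_17:0_17:0","spiked",221855,207918,211270,202806,212780,216586
"TAG 48:0 d5","neat",189066,195239,191359,185473,185713,183444
"TAG 48:0 d5","unspiked",16013,14418,14606,13934,14865,14420
"TAG 48:0 d5","spiked",180938,191863,183799,191816,191453,182658
"PC 13:0_13:0","neat",143416,152885,147399,147418,158953,155752
"PC 13:0_13:0","unspiked",11236,12998,11222,12156,13021,12654
"PC 13:0_13:0","spiked",154866,146443,150046,153076,139757,153338
"PE 14:0_14:0","neat",116208,118408,115028,121293,125459,121704
"PE 14:0_14:0","unspiked",9871,9283,9629,9419,9366,9880
"PE 14:0_14:0","spiked",115602,122338,120781,119513,122631,117875
"PI 12:0_13:0","neat",94862,97022,92288,91500,91252,89722
"PI 12:0_13:0","unspiked",6853,6742,6889,7332,7267,7506
"PI 12:0_13:0","spiked",87422,87515,85158,85200,81858,84464
"PS 14:0_14:0","neat",78211,78884,76444,75655,86338,79569
"PS 14:0_14:0","unspiked",7141,6554,6787,6393,5980,6040
"PS 14:0_14:0","spiked",75243,72880,73720,77397,72620,76362
"LPC 13:0","neat",58986,61913,58444,57427,60012,61688
"LPC 13:0","unspiked",5098,4656,4815,4825,4863,5198
"LPC 13:0","spiked",47986,48377,46707,46180,47637,45826
"LPE 14:0","neat",49514,52419,51049,51868,47378,47551
"LPE 14:0","unspiked",3755,3985,3628,4191,4260,3942
"LPE 14:0","spiked",37090,41995,39622,40965,40807,44477
"SM d18:1/6:0","neat",140964,137421,141306,137198,135937,138343
"SM d18:1/6:0","unspiked",12031,10440,11297,10556,11291,11238
"SM d18:1/6:0","spiked",145967,142760,131603,147905,135051,135808
"Cer d18:1/17:0","neat",70278,72263,69550,69088,72402,72400
"Cer d18:1/17:0","unspiked",5708,5689,6502,5439,5721,6451
"Cer d18:1/17:0","spiked",72897,67859,69358,66567,65241,71951
"Hex1Cer d18:1/8:0","neat",65478,64753,67199,64173,63548,63083
"Hex1Cer d18:1/8:0","unspiked",4752,5791,5713,5340,5243,5255
"Hex1Cer d18:1/8:0","spiked",60649,64780,63017,68132,62873,65161
"GM3 d18:1/18:0 d3","neat",42731,40103,39318,38424,40378,41907
"GM3 d18:1/18:0 d3","unspiked",3512,3071,3302,3377,3188,3208
"GM3 d18:1/18:0 d3","spiked",38570,39001,38960,37883,36594,38747
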