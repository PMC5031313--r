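"state","cost_total","lower_90","upper_90","per_capita","per_capita_lower","per_capita_upper","cost_65plus","cost_65plus_lower","cost_65plus_upper","per_capita_65plus","per_capita_65plus_lower","per_capita_65plus_upper"
"Alabama",267015920,218238816,323718080,54,44,66,71968488,62916296,81849280,96,84,109
"Alaska",32631558,25892390,39326528,41,33,50,7091582,6163682,8092297,100,87,114
"Arizona",303535808,241320896,370999104,44,35,54,95796376,84122576,108166688,89,78,100
"Arkansas",146998480,118559656,179101792,49,39,59,42740348,37592736,48380896,91,80,103
"California",1779335552,1434078336,1434078336,44,36,53,492571488,428707904,560523904,97,85,111
"Colorado",236723888,185570432,291377216,43,34,53,60418264,53125408,68220496,88,77,99
"Connecticut",177031824,142032288,215684848,48,39,59,49822676,43874712,56343884,89,78,101
"Delaware",50753544,41130608,61685976,53,43,64,14656278,12840961,16652654,95,83,107
"District of Columbia",44293000,35309632,53729096,65,52,79,9390157,8006677,10949040,124,106,144
"Florida",1061692992,859051456,1287815168,52,42,63,346982176,305121152,392876000,91,80,103
"Georgia",549650240,444891712,665635456,53,43,65,125373000,109428864,143051600,99,87,113
"Hawaii",84797592,66575184,103866368,45,35,55,31726716,26612724,37030492,124,104,145
"Idaho",67714216,52564512,83998560,40,31,50,20377088,17931348,22986322,87,76,98
"Illinois",630516352,509110272,768060928,48,39,58,167950480,147227424,190724032,93,82,106
"Indiana",304094912,242018656,373562528,45,36,56,83279520,73321136,94107792,88,77,99
"Iowa",137240256,107786048,169422864,43,34,54,41757180,36806488,47026708,85,75,95
"Kansas",129648296,102516616,159097952,43,34,53,36615524,32236882,41342440,87,77,99
"Kentucky",205388224,163026080,252522880,46,36,56,57608312,50715280,65077224,87,77,99
"Louisiana",261012528,212181280,316236928,55,45,67,63654108,55524952,72593456,100,87,114
"Maine",62515084,48874552,77913512,46,36,58,20817142,18348924,23451438,85,75,96
"Maryland",340440992,277990464,409653696,55,45,67,84344672,73401728,96475184,102,88,116
"Massachusetts",322609120,258172224,395243136,47,37,57,90326104,79511424,102069488,88,78,100
"Michigan",497511168,400754560,606731904,49,39,60,141127008,124048904,159935344,92,80,104
"Minnesota",245311456,194417696,301950656,44,35,54,67790480,59669016,76483360,87,76,98
"Mississippi",173332464,140200848,210837024,57,46,70,43148340,37627920,49206216,100,87,114
"Missouri",293064128,235087856,358443904,47,38,58,84043568,74010832,95064560,89,79,101
"Montana",46296536,36322560,57078144,44,35,54,15137121,13304658,17096334,88,77,99
"Nebraska",82157576,64721576,100969312,43,34,53,23409542,20614788,26391860,86,76,97
"Nevada",135586784,109772848,164513984,46,37,55,38848784,33960664,44128448,95,83,108
"New Hampshire",60858696,47326696,75956088,45,35,56,18116064,15962738,20413906,85,75,96
"New Jersey",448747296,364723456,542632384,49,40,59,124254664,108837232,141066176,94,82,107
"New York",1025842688,833381888,1238834688,51,41,61,28918304,25400244,32649880,90,79,101
"New Mexico",92487560,73218128,112826432,43,34,53,281050912,245926528,319588416,96,84,109
"North Carolina",525503904,426140608,638225536,52,42,63,140348592,122879288,159536720,95,83,108
"North Dakota",32036090,24984198,39484780,42,33,52,9025682,7951615,10175980,86,75,97
"Ohio",568419008,456125568,695443200,48,38,59,162532560,143131392,183908032,90,79,102
"Oklahoma",183027776,147502800,221717952,44,36,54,53003912,46518312,60020880,92,81,104
"Oregon",181030208,142299376,222707280,44,34,54,56126272,49330920,63368580,87,77,99
"Pennsylvania",636048768,512372960,777165632,49,39,60,190557488,167795824,215459136,89,78,100
"Rhode Island",50781376,40460728,62291192,47,37,57,14485806,12753338,16341575,87,76,98
"South Carolina",271378304,221157280,328374400,55,45,67,74782944,65337404,85138232,98,85,111
"South Dakota",37129324,29218250,45537900,43,33,52,11368387,10000352,12835862,87,76,98
"Tennessee",330590784,266203136,403762624,50,40,61,90469296,79539880,102467152,91,80,103
"Texas",1212168064,975931200,1480503552,44,36,54,287602336,252581472,325920928,92,81,104
"Utah",108943024,84096976,135957696,36,28,45,25761394,22665116,29081360,87,76,98
"Vermont",29008612,22573144,36129312,45,35,57,9114263,8031334,10268387,85,75,96
"Virginia",434973696,352716416,527751872,51,41,62,111438624,97540704,126780296,96,84,110
"Washington",323034816,256845472,393669248,44,35,53,90820496,79796952,102606704,90,79,102
"West Virginia",87293488,68884136,107860592,46,37,57,28455174,25064588,32076444,86,76,97
"Wisconsin",265044816,210049024,326058368,45,36,56,76195096,67076304,85966336,87,76,98
"Wyoming",25271312,19628788,31385668,42,33,53,7177984,6313404,8100528,87,77,98
"National",15598520320,12632376320,18970537984,48,39,58,4320378880,3790066688,4900164608,93,81,105
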