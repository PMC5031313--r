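"state","stroke","copd","chf","colorectal_cancer","breast_cancer","dementia","musculoskeletal","depression","total"
"Alabama",22,30.7,8.7,3,1.1,152.4,10.6,38.4,267
"Alaska",1.9,3,1,0.3,0.1,17.8,1.8,6.7,32.6
"Arizona",21.8,33.8,11.8,4.1,1.8,165.2,15.3,49.7,303.5
"Arkansas",11.5,16.8,5.3,1.8,0.8,82.1,6.5,22.1,147
"California",120.8,184.7,56.7,21.5,8.6,988.6,91.3,307,1779.3
"Colorado",16.3,25,8.2,2.6,1.1,130.6,12.4,40.4,236.7
"Connecticut",13.1,19.9,6.5,2.1,0.9,98.2,8.7,27.6,177
"Delaware",4.1,5.8,1.8,0.6,0.2,28.7,2.1,7.4,50.8
"District of Columbia",3.9,4.8,1,0.3,0.1,26.5,1.4,6.4,44.3
"Florida",84.7,125.9,41.2,14.5,6.1,591.8,45.8,151.6,1061.7
"Georgia",43.4,61.4,15.8,5.2,1.9,317.3,21.9,82.8,549.7
"Hawaii",4.3,7.9,2.3,1.5,0.4,46.8,4.3,17.2,84.8
"Idaho",4.8,7.4,2.7,0.9,0.4,36.8,3.6,11.2,67.7
"Illinois",47.7,69.3,21,7,2.9,354.4,29.3,98.9,630.5
"Indiana",22.6,33.8,11,3.5,1.6,168.8,15,47.9,304.1
"Iowa",10,15.5,5.5,1.8,0.8,74.8,7.2,21.7,137.2
"Kansas",9.4,14.3,4.8,1.5,0.7,71.4,6.6,21,129.6
"Kentucky",15.3,23,7.6,2.4,1.1,113.8,10.2,32,205.4
"Louisiana",21.3,29.6,7.8,2.6,0.9,150.8,10.1,37.9,261
"Maine",4.6,7.2,2.8,0.9,0.4,33.9,3.3,9.5,62.5
"Maryland",27.4,37.9,10.1,3.5,1.2,196.3,13.4,50.5,340.4
"Massachusetts",23.4,35.7,11.7,3.8,1.8,177.9,16.6,51.8,322.6
"Michigan",38.3,56.1,18,5.9,2.5,278.3,23,75.4,497.5
"Minnesota",17.1,26.8,9.2,2.9,1.3,134.2,13,40.8,245.3
"Mississippi",14.6,20,5.2,1.8,0.6,100.5,6.3,24.4,173.3
"Missouri",22.3,33.1,10.7,3.5,1.5,163.2,13.8,44.9,293.1
"Montana",3.3,5.1,2,0.6,0.3,25,2.4,7.5,46.3
"Nebraska",5.9,9.1,3.1,1,0.5,45,4.2,13.4,82.2
"Nevada",9.5,14.6,4.7,1.7,0.6,75.7,6.5,22.3,135.6
"New Hampshire",4.3,6.7,2.5,0.8,0.4,33.1,3.3,9.7,60.9
"New Jersey",33.6,49.6,15.2,5.2,2.2,251.2,21.3,70.5,448.7
"New York",78.4,113.4,33.4,11.7,4.7,579.9,46.2,158.2,1025.8
"New Mexico",6.5,10.1,3.6,1.2,0.5,50.2,4.8,15.6,92.5
"North Carolina",42,59.2,17.2,5.8,2.3,298,22.2,79,525.5
"North Dakota",2.2,3.5,1.2,0.4,0.2,17.4,1.7,5.5,32
"Ohio",43.8,64.4,20.8,6.7,2.9,317.2,26.7,86,568.4
"Oklahoma",12.9,19.8,6.4,2.3,1,100.1,9.2,31.4,183
"Oregon",12.9,20,7.2,2.4,1.1,98.5,9.5,29.5,181
"Pennsylvania",48.7,72.9,24.1,7.9,3.6,352.9,30.2,95.8,636
"Rhode Island",3.7,5.7,1.9,0.6,0.3,27.9,2.6,8.1,50.8
"South Carolina",22.6,31.2,8.9,3.1,1.1,155.3,10.5,38.6,271.4
"South Dakota",2.6,4.1,1.5,0.5,0.2,19.9,2,6.4,37.1
"Tennessee",25.8,37.5,11.6,3.8,1.6,185.8,14.8,49.8,330.6
"Texas",87.4,129.2,37.8,12.2,5.1,680.7,58.6,201,1212.2
"Utah",7.3,11,3.5,1.1,0.5,59.7,5.9,20,108.9
"Vermont",2.1,3.3,1.2,0.4,0.2,15.8,1.6,4.5,29
"Virginia",33.4,47.8,13.7,4.7,1.8,246.7,19.2,67.7,435
"Washington",22,34.4,11.6,3.9,1.7,177,17.1,55.4,323
"West Virginia",6.6,10.1,3.7,1.2,0.5,47.8,4.4,13,87.3
"Wisconsin",19.2,29.5,10.2,3.2,1.5,145.4,13.6,42.3,265
"Wyoming",1.8,2.7,1,0.3,0.1,13.9,1.3,4.2,25.3
"National",1165,1724,536,182,76,8721,733,2460,15599
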