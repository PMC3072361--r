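"day","metric","mean","sd"
0,"cell_number",1.6,0.448
1,"cell_number",2.32,0.6496
2,"cell_number",3.364,0.94192
3,"cell_number",4.8778,1.365784
4,"cell_number",7.07281,1.9803868
5,"cell_number",10.2555745,2.87156086
6,"cell_number",14.870583025,4.163763247
7,"cell_number",16.655052988,4.66341483664
8,"cell_number",18.439522951,5.16306642628
9,"cell_number",20.223992914,5.66271801592
10,"cell_number",22.008462877,6.16236960556
0,"cyst_area",82,24.6
1,"cyst_area",123,36.9
2,"cyst_area",184.5,55.35
3,"cyst_area",276.75,83.025
4,"cyst_area",415.125,124.5375
5,"cyst_area",622.6875,186.80625
6,"cyst_area",934.03125,280.209375
7,"cyst_area",1401.046875,420.3140625
8,"cyst_area",2101.5703125,630.47109375
9,"cyst_area",2311.72734375,693.518203125
10,"cyst_area",2521.884375,756.5653125
0,"lumen_area",0.5,0.175
1,"lumen_area",11.07,3.8745
2,"lumen_area",33.21,11.6235
3,"lumen_area",74.7225,26.152875
4,"lumen_area",149.445,52.30575
5,"lumen_area",280.209375,98.07328125
6,"lumen_area",504.376875,176.53190625
7,"lumen_area",770.57578125,269.7015234375
8,"lumen_area",1155.863671875,404.55228515625
9,"lumen_area",1271.4500390625,445.007513671875
10,"lumen_area",1387.03640625,485.4627421875
0,"mean_cell_area",51.25,12.8125
1,"mean_cell_area",48.2456896551724,12.0614224137931
2,"mean_cell_area",44.9732461355529,11.2433115338882
3,"mean_cell_area",41.4177498052401,10.35443745131
4,"mean_cell_area",37.5635709145304,9.39089272863261
5,"mean_cell_area",33.3943383669048,8.34858459172619
6,"mean_cell_area",28.8929071763815,7.22322679409539
7,"mean_cell_area",37.8546435249564,9.4636608812391
8,"mean_cell_area",51.2869363886506,12.8217340971627
9,"mean_cell_area",51.4377803192055,12.8594450798014
10,"mean_cell_area",51.5641630718325,12.8910407679581
0,"cellular_to_cyst_ratio",1,0.12
1,"cellular_to_cyst_ratio",0.91,0.1092
2,"cellular_to_cyst_ratio",0.82,0.0984
3,"cellular_to_cyst_ratio",0.73,0.0876
4,"cellular_to_cyst_ratio",0.64,0.0768
5,"cellular_to_cyst_ratio",0.55,0.066
6,"cellular_to_cyst_ratio",0.46,0.0552
7,"cellular_to_cyst_ratio",0.45,0.054
8,"cellular_to_cyst_ratio",0.45,0.054
9,"cellular_to_cyst_ratio",0.45,0.054
10,"cellular_to_cyst_ratio",0.45,0.054
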