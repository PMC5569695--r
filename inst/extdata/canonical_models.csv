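model_no,k,predictors,adj_r2_csdm15,f_csdm15,adj_r2_mps,f_mps
1,1,peak_g,0.36,152,0.43,192
2,1,v_i,0.40,181,0.45,206
3,1,dv_r,0.44,210,0.48,234
4,1,v_r,0.46,229,0.51,260
5,1,dw_r,0.86,1629,0.89,2023
6,1,w_r,0.82,1252,0.83,1239
7,1,alpha_r,0.11,33,0.17,49
8,2,peak_g;v_i,0.44,107,0.48,116
9,2,peak_g;dv_r,0.48,123,0.51,132
10,2,peak_g;dw_r,0.86,841,0.89,1008
11,2,peak_g;w_r,0.83,658,0.85,735
12,2,v_i;dw_r,0.86,812,0.89,1009
13,2,dv_r;dw_r,0.85,731,0.86,788
14,2,v_r;dw_r,0.84,713,0.86,772
15,2,v_i;w_r,0.86,813,0.89,1008
16,2,peak_g;alpha_r,0.37,75,0.44,95
17,2,v_i;alpha_r,0.46,106,0.49,116
18,2,dv_r;alpha_r,0.48,116,0.52,129
19,2,alpha_r;dw_r,0.87,851,0.89,1025
20,2,alpha_r;w_r,0.83,621,0.84,640
21,3,peak_g;dv_r;dw_r,0.88,638,0.89,686
22,3,peak_g;dv_r;w_r,0.86,544,0.86,526
23,3,peak_g;v_r;dw_r,0.87,619,0.89,679
24,3,peak_g;v_r;w_r,0.85,512,0.86,514
25,3,dw_x;dw_y;dw_z,0.87,593,0.89,720
26,3,w_x;w_y;w_z,0.86,525,0.87,556
27,3,peak_g;dv_r;alpha_r,0.46,73,0.49,77
28,3,peak_g;v_r;alpha_r,0.50,84,0.52,87
29,4,peak_g;w_x;w_y;w_z,0.86,394,0.87,417
30,4,peak_g;dw_x;dw_y;dw_z,0.87,443,0.89,541
31,4,peak_g;v_i;dv_r;w_r,0.86,407,0.86,397
32,4,peak_g;v_i;v_r;dw_r,0.88,482,0.89,514
33,4,peak_g;v_i;dv_r;dw_r,0.89,525,0.89,530
34,4,peak_g;dv_r;v_r;w_r,0.85,391,0.86,398
35,4,peak_g;v_i;dv_r;alpha_r,0.49,60,0.50,61
36,4,peak_g;v_i;v_r;alpha_r,0.55,78,0.56,78
37,5,peak_g;dv_r;w_x;w_y;w_z,0.87,362,0.90,447
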