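transect_id,occasion,distance_m,group_size
S001_L1_P1,occ1,41.621000000000002,2
S001_L1_P2,occ1,104.973,2
S001_L1_P2,occ1,42.866,1
S001_L2_P2,occ1,61.774999999999999,4
S001_L2_P3,occ1,39.121000000000002,1
S001_L4_P1,occ1,69.620999999999995,3
S001_L4_P2,occ1,52.978999999999999,2
S001_L4_P4,occ1,35.067999999999998,2
S001_L5_P2,occ1,30.548999999999999,3
S001_L5_P2,occ1,15.438000000000001,3
S001_L6_P1,occ1,16.574999999999999,1
S002_L1_P3,occ1,66.641000000000005,3
S002_L1_P3,occ1,52.637,2
S002_L1_P3,occ1,53.136000000000003,3
S002_L1_P4,occ1,43.811999999999998,4
S002_L1_P4,occ1,46.725999999999999,1
S002_L2_P2,occ1,123.18899999999999,1
S002_L2_P2,occ1,32.594000000000001,2
S002_L2_P3,occ1,53.509999999999998,3
S002_L2_P3,occ1,55.286999999999999,2
S002_L2_P4,occ1,25.698,2
S002_L3_P1,occ1,108.42,3
S002_L3_P1,occ1,85.635999999999996,1
S002_L3_P2,occ1,33.054000000000002,4
S002_L4_P1,occ1,46.159999999999997,1
S002_L4_P2,occ1,61.871000000000002,1
S002_L4_P2,occ1,13.411,3
S002_L4_P4,occ1,66.093999999999994,1
S002_L4_P4,occ1,93.477000000000004,1
S002_L5_P1,occ1,48.261000000000003,1
S002_L5_P1,occ1,48.923000000000002,2
S002_L5_P2,occ1,21.193000000000001,3
S002_L5_P3,occ1,62.956000000000003,3
S002_L5_P4,occ1,56.262,1
S002_L5_P4,occ1,49.113,2
S002_L5_P4,occ1,29.795999999999999,2
S002_L6_P4,occ1,72.200999999999993,1
S002_L6_P4,occ1,10.361000000000001,2
S002_L6_P4,occ1,31.417999999999999,1
S003_L2_P1,occ1,37.569000000000003,1
S003_L4_P3,occ1,84.070999999999998,2
S003_L5_P2,occ1,96.772000000000006,1
S003_L5_P4,occ1,40.094999999999999,2
S003_L6_P1,occ1,13.984,1
S003_L6_P3,occ1,28.393999999999998,1
S004_L2_P4,occ1,28.585000000000001,4
S004_L2_P4,occ1,3.081,3
S004_L3_P2,occ1,67.394000000000005,2
S004_L3_P3,occ1,71.602000000000004,1
S004_L3_P4,occ1,66.564999999999998,2
S004_L3_P4,occ1,21.166,1
S004_L3_P4,occ1,21.463000000000001,1
S004_L4_P1,occ1,79.739999999999995,2
S004_L4_P1,occ1,27.489000000000001,1
S004_L4_P3,occ1,80.146000000000001,1
S004_L4_P4,occ1,43.363,1
S004_L5_P1,occ1,43.090000000000003,1
S004_L5_P2,occ1,49.887,3
S004_L5_P2,occ1,71.251999999999995,2
S004_L5_P3,occ1,59.683,1
S004_L5_P4,occ1,40.018000000000001,3
S005_L3_P2,occ1,41.524000000000001,1
S005_L3_P4,occ1,52.406999999999996,2
S005_L4_P2,occ1,51.170999999999999,2
S005_L4_P4,occ1,46.164999999999999,1
S005_L5_P3,occ1,106.872,1
S005_L5_P4,occ1,22.483000000000001,1
S005_L6_P3,occ1,28.257000000000001,1
S005_L6_P4,occ1,100.73699999999999,1
S006_L1_P2,occ1,64.436000000000007,2
S006_L1_P3,occ1,91.968000000000004,4
S006_L2_P3,occ1,45.996000000000002,4
S006_L2_P4,occ1,23.478000000000002,2
S006_L2_P4,occ1,59.299999999999997,2
S006_L3_P2,occ1,98.504000000000005,1
S006_L3_P3,occ1,34.564,2
S006_L3_P4,occ1,39.564,2
S006_L4_P4,occ1,48.911000000000001,1
S006_L4_P4,occ1,21.375,1
S006_L5_P2,occ1,23.277000000000001,1
S006_L5_P4,occ1,26.658999999999999,2
S001_L1_P3,occ2,67.150000000000006,3
S001_L2_P2,occ2,48.378,1
S001_L2_P4,occ2,24.716999999999999,1
S001_L2_P4,occ2,50.389000000000003,1
S001_L3_P1,occ2,101.318,2
S001_L3_P2,occ2,112.33499999999999,1
S001_L3_P4,occ2,49.186,3
S001_L4_P1,occ2,30.535,1
S001_L4_P2,occ2,28.350999999999999,1
S001_L4_P4,occ2,19.783999999999999,1
S001_L4_P4,occ2,38.722999999999999,1
S001_L5_P1,occ2,67.122,2
S001_L5_P4,occ2,72.281000000000006,1
S001_L6_P1,occ2,18.977,1
S001_L6_P3,occ2,38.590000000000003,3
S001_L6_P3,occ2,60.484000000000002,1
S001_L6_P3,occ2,86.319999999999993,2
S002_L1_P2,occ2,51.603999999999999,3
S002_L1_P3,occ2,81.777000000000001,2
S002_L2_P2,occ2,72.281000000000006,3
S002_L2_P3,occ2,77.057000000000002,3
S002_L2_P4,occ2,29.245999999999999,2
S002_L2_P4,occ2,66.218999999999994,3
S002_L3_P1,occ2,88.284999999999997,3
S002_L3_P1,occ2,15.029999999999999,2
S002_L3_P2,occ2,46.195,3
S002_L3_P3,occ2,29.183,3
S002_L4_P1,occ2,94.733999999999995,1
S002_L4_P1,occ2,64.771000000000001,2
S002_L4_P1,occ2,23.190000000000001,2
S002_L4_P2,occ2,55.003999999999998,3
S002_L4_P2,occ2,87.039000000000001,1
S002_L4_P2,occ2,53.899000000000001,2
S002_L4_P3,occ2,45.609999999999999,3
S002_L4_P3,occ2,10.218999999999999,1
S002_L4_P3,occ2,52.155999999999999,2
S002_L4_P4,occ2,37.073999999999998,2
S002_L5_P1,occ2,43.363999999999997,5
S002_L5_P2,occ2,73.397000000000006,4
S002_L5_P3,occ2,54.75,2
S002_L5_P4,occ2,35.246000000000002,3
S002_L5_P4,occ2,44.075000000000003,1
S002_L5_P4,occ2,28.228999999999999,2
S002_L5_P4,occ2,111.57899999999999,1
S002_L6_P1,occ2,19.164999999999999,1
S002_L6_P1,occ2,85.894999999999996,2
S002_L6_P1,occ2,58.665999999999997,1
S002_L6_P1,occ2,9.6150000000000002,4
S002_L6_P1,occ2,40.738999999999997,2
S003_L1_P1,occ2,55.395000000000003,1
S003_L1_P3,occ2,44.082999999999998,3
S003_L2_P3,occ2,19.23,1
S003_L2_P3,occ2,109.127,1
S003_L2_P4,occ2,52.554000000000002,2
S003_L6_P1,occ2,73.036000000000001,2
S003_L6_P1,occ2,58.219000000000001,1
S003_L6_P2,occ2,19.864000000000001,3
S004_L1_P4,occ2,100.992,3
S004_L2_P1,occ2,65.451999999999998,1
S004_L2_P3,occ2,40.691000000000003,1
S004_L2_P3,occ2,70.697000000000003,1
S004_L2_P4,occ2,35.912999999999997,2
S004_L2_P4,occ2,62.200000000000003,1
S004_L2_P4,occ2,109.77200000000001,1
S004_L3_P3,occ2,22.611000000000001,3
S004_L3_P3,occ2,92.102000000000004,1
S004_L3_P3,occ2,44.340000000000003,3
S004_L3_P4,occ2,27.751999999999999,1
S004_L3_P4,occ2,31.206,3
S004_L3_P4,occ2,21.678000000000001,1
S004_L4_P1,occ2,69.096000000000004,2
S004_L4_P1,occ2,51.972999999999999,1
S004_L4_P2,occ2,35.853000000000002,4
S004_L4_P2,occ2,50.438000000000002,3
S004_L4_P4,occ2,45.786999999999999,1
S004_L5_P1,occ2,113.288,1
S004_L6_P1,occ2,79.608000000000004,1
S004_L6_P4,occ2,12.016,2
S004_L6_P4,occ2,119.8,2
S005_L1_P1,occ2,98.932000000000002,1
S005_L1_P2,occ2,43.805999999999997,2
S005_L1_P4,occ2,45.661999999999999,1
S005_L1_P4,occ2,47.213999999999999,1
S005_L2_P4,occ2,51.722999999999999,1
S005_L3_P1,occ2,58.905999999999999,1
S005_L3_P3,occ2,80.224999999999994,2
S005_L6_P3,occ2,88.962000000000003,1
S005_L6_P4,occ2,135.16,4
S006_L1_P2,occ2,51.798000000000002,1
S006_L1_P2,occ2,14.890000000000001,2
S006_L1_P2,occ2,12.211,1
S006_L1_P4,occ2,29.625,2
S006_L1_P4,occ2,58.161000000000001,3
S006_L1_P4,occ2,53.470999999999997,1
S006_L2_P2,occ2,49.484999999999999,1
S006_L3_P1,occ2,65.631,1
S006_L3_P2,occ2,27.266999999999999,3
S006_L3_P3,occ2,34.695,3
S006_L3_P3,occ2,71.564999999999998,2
S006_L3_P4,occ2,122.30200000000001,2
S006_L4_P2,occ2,57.451999999999998,1
S006_L4_P2,occ2,7.0380000000000003,2
S006_L4_P3,occ2,69.245000000000005,2
S006_L4_P3,occ2,28.553999999999998,3
S006_L5_P1,occ2,32.098999999999997,3
S006_L6_P1,occ2,60.811,3
S006_L6_P3,occ2,41.009999999999998,4
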