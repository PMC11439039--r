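n,En_H,Es_GA2,En_GA2,En_DD,Es_ABC2
2,33.9739,61.8001,33.0159,171.7260,31.1840
3,49.5709,87.8085,47.0358,257.8670,43.8298
4,55.4696,100.3755,53.8542,293.4041,48.1860
5,75.1084,137.9933,72.8540,401.5943,61.2726
6,85.3010,155.1719,81.9266,460.3674,68.9791
7,100.7379,181.9450,96.5166,545.7397,80.7527
8,110.8029,201.1642,106.5684,603.7799,88.2220
9,126.3356,230.1936,121.6045,689.7301,99.6331
10,136.5202,250.8521,132.2422,748.3675,106.8188
11,152.0197,282.0789,147.9012,834.0704,118.1205
12,162.1132,302.5011,158.2979,892.3617,125.3207
13,177.6372,333.4137,173.9538,978.1854,136.5843
14,187.7551,354.0322,184.5034,1036.5700,143.7324
15,203.2384,385.2485,200.1778,1122.2477,154.9428
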