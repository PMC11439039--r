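n,En_H,Es_GA2,En_GA2,En_DD,Es_ABC2
1,32.6030,63.6081,33.5744,166.0818,28.3634
2,75.8024,151.8531,77.6014,410.3461,58.4956
3,136.6019,280.5523,141.0622,760.2151,100.2979
4,214.9346,442.9552,221.5188,1215.3431,154.4797
5,310.9049,644.8226,321.0271,1776.4108,220.5881
6,424.5764,879.8015,436.9177,2443.6358,298.7547
7,556.0342,1150.0168,571.3838,3217.4930,388.8993
8,705.2066,1465.6511,726.9697,4097.6440,490.8686
9,870.5932,1801.4729,893.6640,5077.6889,604.0102
10,1055.0350,2190.3040,1085.3135,6170.4290,730.0064
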