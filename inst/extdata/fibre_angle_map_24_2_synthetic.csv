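"x_deg","y_deg","fibre_angle_deg"
-9,21,141.633
-3,21,133.452
3,21,122.276
9,21,107.526
-15,15,156.571
-9,15,151.557
-3,15,144.162
3,15,132.709
9,15,114.775
15,15,90
-21,9,168.996
-15,9,166.866
-9,9,163.74
-3,9,158.749
3,9,149.744
9,9,130.601
15,9,90
21,9,49.399
-27,3,178
-21,3,178
-15,3,178
-9,3,177.614
-3,3,176.82
3,3,175.236
9,3,170.538
21,3,9.462
-27,-3,-178
-21,-3,-178
-15,-3,-178
-9,-3,-177.614
-3,-3,-176.82
3,-3,-175.236
9,-3,-170.538
21,-3,-9.462
-21,-9,-168.996
-15,-9,-166.866
-9,-9,-163.74
-3,-9,-158.749
3,-9,-149.744
9,-9,-130.601
15,-9,-90
21,-9,-49.399
-15,-15,-156.571
-9,-15,-151.557
-3,-15,-144.162
3,-15,-132.709
9,-15,-114.775
15,-15,-90
-9,-21,-141.633
-3,-21,-133.452
3,-21,-122.276
9,-21,-107.526
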