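{"levels":[0,1,2,3,4,5,6,7,8,9,10,11,12,13,14,15,16,17,18,19,20,21,22,23,24,25,26,27,28,29,30,31,32,33,34,35],"K":2,"transformKnot":1,"weights":[[0.738748916015341,0.261251083984659],[0.39809482994882,0.60190517005118],[0.247579120046156,0.752420879953844],[0.195588169126672,0.804411830873328],[0.149095235079453,0.850904764920547],[0.0790763779695387,0.920923622030461],[0.0764434266561353,0.923556573343865],[0.0652045816829993,0.934795418317001],[0.026313104968926,0.973686895031074],[0.0279241801918805,0.97207581980812],[0.0312238579821479,0.968776142017852],[0.0172719789461712,0.982728021053829],[0.0306492683135394,0.969350731686461],[0.0279702970293413,0.972029702970659],[0.020637657367872,0.979362342632128],[0.0193224191259884,0.980677580874012],[0.0186487778505557,0.981351222149444],[0.237616968142052,0.762383031857948],[0.24528316952996,0.75471683047004],[0.220795384157949,0.779204615842051],[0.159133835862561,0.840866164137439],[0.209289010613855,0.790710989386144],[0.141052003423397,0.858947996576603],[0.118074112212318,0.881925887787682],[0.102946053952679,0.897053946047321],[0.0794400530981925,0.920559946901808],[0.0830510963807711,0.916948903619229],[0.077657534241162,0.922342465758838],[0.052284545104213,0.947715454895787],[0.0372592574181323,0.962740742581868],[0.0358715420436409,0.964128457956359],[0.0257164670195777,0.974283532980422],[0.0263494414205951,0.973650558579405],[0.0179725320772798,0.98202746792272],[0.00813618337114998,0.99186381662885],[0.0358076073431649,0.964192392656835]],"alphas":[[100,0.877228911093363],[100,1.01472529534388],[100,1.13400210999644],[100,1.17516913813832],[100,1.30349541356392],[100,1.33131930003471],[100,1.38179370783849],[100,1.5103624483522],[100,1.66963317262114],[100,1.67986495962433],[100,1.59328517495809],[100,1.75253631311629],[100,2.08038916294215],[100,1.95890612909374],[100,1.96587768526223],[100,2.19194844412952],[100,2.08838239411977],[1.39310422850589,4.43404506829755],[1.34156720433661,4.31007054656078],[1.36033676018206,4.41909579038538],[1.31731706488825,5.4127550984902],[1.71113258987074,5.82377499152501],[1.37967134524995,6.56230790973444],[1.59722840719774,7.39172862958356],[1.29652511229221,7.54197108625165],[1.32666784800304,8.56707773335284],[1.93605914040445,9.78206080666732],[1.65589923257135,11.141366381353],[1.34832280683455,12.4233130513916],[1.62036980506021,14.1398510857398],[1.53749286671677,14.7635310942291],[1.25744710544154,17.0088805038977],[1.28557985847358,19.0621886300622],[1.62667705348827,22.2582860526817],[1.48280129283062,27.3160535859761],[0.745590739650681,36.0985827581866]],"betas":[[0.367879441171442,4.8500391991777],[0.367879441171442,9.81970411837983],[0.367879441171442,12.4188102533677],[0.367879441171442,12.2251124072816],[0.367879441171442,14.9985527525793],[0.367879441171442,14.1343243290084],[0.367879441171442,14.1124377400713],[0.367879441171442,15.9581585934502],[0.367879441171442,16.1481065583051],[0.367879441171442,16.3196002008699],[0.367879441171442,15.3631324798382],[0.367879441171442,16.2243535354035],[0.367879441171442,17.6707586973413],[0.367879441171442,16.6023059281837],[0.367879441171442,16.6713649155057],[0.367879441171442,18.4815910939116],[0.367879441171442,17.3137529956769],[9.26475298853805,22.2114869607652],[8.91368985386703,21.9188070801743],[9.5731673856816,22.5435129476929],[8.80984805141775,23.5804168649442],[11.6091204515971,24.2330021309634],[10.869923027365,25.1228677680079],[12.0667796010689,26.1858865808028],[9.81912463914681,26.5511412204688],[10.9503889758598,27.5528686652566],[15.1675054627866,27.9983428865886],[14.2401731645278,28.847174729552],[12.4664793763252,29.3216612310872],[13.8098228703018,30.0271608313269],[9.72048743736253,30.4466653722831],[13.1587374168108,31.2409964126554],[12.8689124251712,31.9453173337293],[13.4292888333325,32.8508052742695],[15.7816419261728,34.0290842702858],[7.21559480529454,34.9200358516242]]}
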