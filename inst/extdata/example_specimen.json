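{
  "schema_version": 1,
  "specimen_id": "EXAMPLE01",
  "side": "R",
  "sex": "unknown",
  "age": {},
  "landmarks": {
    "head_surface": [
      [47.2051326101925, 20.7205190482887, 21.6204724524709],
      [31.2213319385024, 27.8366363371166, 18.646904081841],
      [41.8089895446853, 5.20322798726732, 17.0025781470631],
      [50.218223508098, 34.6798154242732, 14.6668693118582],
      [21.108530098567, 17.2080357892436, 13.2658694291289],
      [58.4218078311056, 10.4011450847518, 9.01465206466803],
      [34.2101728863735, 41.6461890961323, 7.99818546719435],
      [29.7137558036424, 0.988025257613238, 5.15733341198319],
      [62.0797161064459, 28.5365435677505, 2.73424437552484],
      [18.4540323609433, 29.5990465863523, -0.666819467658666],
      [49.7205908000696, -0.591534035053607, -2.41840013395449],
      [47.0260321575772, 42.4184254338169, -4.05906323017907],
      [21.3466705133713, 9.35905725993683, -6.0777406927622],
      [61.3361387254248, 16.6472777748252, -8.25800678278055],
      [28.2868891557438, 37.2165049729688, -11.8213267343033],
      [38.085697313542, 0.943422183651896, -13.421691014213],
      [52.9872658408496, 31.0871850699559, -15.4725209849238],
      [24.8954291481918, 20.2819870181368, -19.1503945218272],
      [48.7128369172022, 12.0024851141722, -19.3862846033598],
      [39.8709114929461, 27.9692710992741, -22.4753087773794]
    ],
    "neck_station_centroids": [
      [-14.3289369951597, 0.696553334685863, -42.3453506813987],
      [-1.18870524815125, 5.82942819024897, -32.3524341040542],
      [12.8881186305935, 10.454618713097, -21.2310667335444],
      [26.8473421045205, 15.1971349044957, -10.1275184491173],
      [39.9137879296987, 20.4535871227576, -0.618322336877767]
    ],
    "canal_centroids": [
      [-0.00577958223988579, -0.615787191867954, 0.0956486120703394],
      [-0.746531654676397, 0.0715653938874541, -9.49630521371493],
      [-0.0297254304444566, -0.577114639224331, -19.8089275345307],
      [-0.248023992342472, -0.503239152478956, -29.1959889682442],
      [-0.699544520144625, -1.04700854810371, -39.9460910869389],
      [-0.53200825979098, -0.709926743802099, -49.6598860661024],
      [-0.163078884443622, -0.720958189554449, -60.1805075160341],
      [-0.233297840225361, -2.48053093004031, -70.1195437396289],
      [0.216322230793575, -3.53077825011981, -79.407096725554],
      [-0.176073619877889, -2.88190514989849, -89.6949375017113],
      [0.446033965704463, -4.32368917657155, -101.077413479657],
      [-0.00560353116566164, -5.0439506127989, -109.679477828155],
      [0.228562929735744, -5.87088604015335, -120.789123394969],
      [-0.883462144176631, -6.87319619262386, -129.80444981311],
      [-0.209107862290505, -8.22285927838671, -140.2677857955],
      [-0.13546841994791, -9.33538293913147, -149.649673911309],
      [-0.0143891874478568, -10.6655191606397, -159.889077756515],
      [0.663850200103701, -11.7967904309174, -168.762559787335],
      [0.568778457058286, -14.2920810319916, -179.148239758076],
      [-0.7636757284033, -14.757639088456, -188.922831931192],
      [-0.59618960758283, -16.8658175725065, -198.168932017805],
      [-0.142992578647552, -17.8718523834123, -208.611764068806],
      [0.546245163939013, -20.1025829525729, -218.036955607951],
      [0.873629820388826, -22.5202187084524, -228.813469992946],
      [-0.0232752499022758, -23.1429264996161, -238.761232744718],
      [0.0235506239651293, -25.1874153393244, -248.354068756091],
      [-0.340756454702282, -27.8687160821436, -257.555455774535],
      [-0.723809415748399, -30.077702408327, -268.188784806454],
      [0.303691046812525, -31.6085276265752, -277.822447502253],
      [0.723027295447779, -34.281965098757, -287.328725040879],
      [0.59726910783324, -36.9951107168531, -296.016146156241],
      [0.213032656505386, -41.0637170485113, -307.686286538101],
      [-0.168237422828338, -42.0432816098329, -316.800877696166],
      [0.608090098335743, -44.9317744263389, -325.824364734023],
      [0.972074570222866, -47.6158094517885, -336.062601003652],
      [0.100527371266552, -50.6110551508628, -344.733043238222],
      [1.21180590423151, -52.6185342309641, -353.962360593563],
      [-0.653632215632539, -56.9456654799621, -363.499593565189],
      [-0.342460088684383, -58.3633605742452, -373.349721334147],
      [0.0891666202305664, -62.0184596923892, -382.033654041355],
      [0.717465729616658, -66.0654774558082, -392.034028407008]
    ],
    "gt_tip": [
      [-9.75975867471919, -0.066593273070091, 8.14035219046985]
    ],
    "neck_lateral_entry": [
      [-14.49705037581, 1.95336962425536, -42.0884299178635]
    ],
    "dicn": [
      [0.286508755403607, -65.3669648926033, -392.659556918519]
    ],
    "condyle_post_medial": [
      [21.5362601118355, -81.3544375234998, -392.047471482477]
    ],
    "condyle_post_lateral": [
      [-21.0332463076417, -80.7582023906916, -393.481170387919]
    ]
  }
}
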