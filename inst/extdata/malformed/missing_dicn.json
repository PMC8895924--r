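{
  "schema_version": 1,
  "specimen_id": "malformed-base",
  "side": "R",
  "sex": "unknown",
  "age": {},
  "landmarks": {
    "head_surface": [
      [52.7091352874508, 20.2414629447813, 18.8102712708341],
      [25.3080627757771, 33.6962733061083, 11.1436046041675],
      [41.9780742474184, -2.35000858413591, 3.4769379375008],
      [53.7937694957304, 38.2389834936309, -4.18972872916586],
      [20.3813083685795, 16.7720050848696, -11.8563953958325],
      [50.7226825475341, 13.4176482788727, -19.5230620624992]
    ],
    "neck_station_centroids": [
      [-14.2490164756657, 0.508308743303631, -41.8697083839902],
      [12.873195224378, 10.3748858440425, -21.1130518899113],
      [39.9954069244218, 20.2414629447813, -0.356395395832529]
    ],
    "canal_centroids": [
      [0, 0, 0],
      [0, -0.550922027293836, -36.3580713243325],
      [0, -2.20318225070878, -72.6827585447274],
      [0, -4.95526355932452, -108.940708210644],
      [0, -8.80463898278526, -145.098628150191],
      [0, -13.7477740115705, -181.123318039108],
      [0, -19.7801298423947, -216.981699885417],
      [0, -26.896167545752, -252.640848401749],
      [0, -35.0893531517791, -288.068021237449],
      [0, -44.3521636497694, -323.230689042718],
      [0, -54.6760938958262, -358.096565337169],
      [0, -66.0516644223148, -392.633636155383]
    ],
    "gt_tip": [
      [-10, 0, 8]
    ],
    "neck_lateral_entry": [
      [-14.2490164756657, 0.508308743303631, -41.8697083839902]
    ],
    "condyle_post_medial": [
      [22, -81.0516644223148, -392.633636155383]
    ],
    "condyle_post_lateral": [
      [-22, -81.0516644223148, -392.633636155383]
    ]
  }
}
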