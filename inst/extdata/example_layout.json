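{
  "electrode_spacing_mm": 0.2,
  "orientation": "CW",
  "wells": {
    "CA1": ["CA1_w01", "CA1_w02", "CA1_w03", "CA1_w04", "CA1_w05", "CA1_w06", "CA1_w07", "CA1_w08", "CA1_w09", "CA1_w10", "CA1_w11", "CA1_w12", "CA1_w13", "CA1_w14", "CA1_w15", "CA1_w16", "CA1_w17", "CA1_w18", "CA1_w19"],
    "CA3": ["CA3_w01", "CA3_w02", "CA3_w03", "CA3_w04", "CA3_w05", "CA3_w06", "CA3_w07", "CA3_w08", "CA3_w09", "CA3_w10", "CA3_w11", "CA3_w12", "CA3_w13", "CA3_w14", "CA3_w15", "CA3_w16", "CA3_w17", "CA3_w18", "CA3_w19"],
    "DG": ["DG_w01", "DG_w02", "DG_w03", "DG_w04", "DG_w05", "DG_w06", "DG_w07", "DG_w08", "DG_w09", "DG_w10", "DG_w11", "DG_w12", "DG_w13", "DG_w14", "DG_w15", "DG_w16", "DG_w17", "DG_w18", "DG_w19"],
    "EC": ["EC_w01", "EC_w02", "EC_w03", "EC_w04", "EC_w05", "EC_w06", "EC_w07", "EC_w08", "EC_w09", "EC_w10", "EC_w11", "EC_w12", "EC_w13", "EC_w14", "EC_w15", "EC_w16", "EC_w17", "EC_w18", "EC_w19"]
  },
  "tunnels": [
    {
      "tunnel_id": "EC_DG_t1",
      "wall": "EC_DG",
      "upstream_electrode": "EC_DG_t1_up",
      "downstream_electrode": "EC_DG_t1_dn"
    },
    {
      "tunnel_id": "EC_DG_t2",
      "wall": "EC_DG",
      "upstream_electrode": "EC_DG_t2_up",
      "downstream_electrode": "EC_DG_t2_dn"
    },
    {
      "tunnel_id": "EC_DG_t3",
      "wall": "EC_DG",
      "upstream_electrode": "EC_DG_t3_up",
      "downstream_electrode": "EC_DG_t3_dn"
    },
    {
      "tunnel_id": "EC_DG_t4",
      "wall": "EC_DG",
      "upstream_electrode": "EC_DG_t4_up",
      "downstream_electrode": "EC_DG_t4_dn"
    },
    {
      "tunnel_id": "EC_DG_t5",
      "wall": "EC_DG",
      "upstream_electrode": "EC_DG_t5_up",
      "downstream_electrode": "EC_DG_t5_dn"
    },
    {
      "tunnel_id": "DG_CA3_t1",
      "wall": "DG_CA3",
      "upstream_electrode": "DG_CA3_t1_up",
      "downstream_electrode": "DG_CA3_t1_dn"
    },
    {
      "tunnel_id": "DG_CA3_t2",
      "wall": "DG_CA3",
      "upstream_electrode": "DG_CA3_t2_up",
      "downstream_electrode": "DG_CA3_t2_dn"
    },
    {
      "tunnel_id": "DG_CA3_t3",
      "wall": "DG_CA3",
      "upstream_electrode": "DG_CA3_t3_up",
      "downstream_electrode": "DG_CA3_t3_dn"
    },
    {
      "tunnel_id": "DG_CA3_t4",
      "wall": "DG_CA3",
      "upstream_electrode": "DG_CA3_t4_up",
      "downstream_electrode": "DG_CA3_t4_dn"
    },
    {
      "tunnel_id": "DG_CA3_t5",
      "wall": "DG_CA3",
      "upstream_electrode": "DG_CA3_t5_up",
      "downstream_electrode": "DG_CA3_t5_dn"
    },
    {
      "tunnel_id": "CA3_CA1_t1",
      "wall": "CA3_CA1",
      "upstream_electrode": "CA3_CA1_t1_up",
      "downstream_electrode": "CA3_CA1_t1_dn"
    },
    {
      "tunnel_id": "CA3_CA1_t2",
      "wall": "CA3_CA1",
      "upstream_electrode": "CA3_CA1_t2_up",
      "downstream_electrode": "CA3_CA1_t2_dn"
    },
    {
      "tunnel_id": "CA3_CA1_t3",
      "wall": "CA3_CA1",
      "upstream_electrode": "CA3_CA1_t3_up",
      "downstream_electrode": "CA3_CA1_t3_dn"
    },
    {
      "tunnel_id": "CA3_CA1_t4",
      "wall": "CA3_CA1",
      "upstream_electrode": "CA3_CA1_t4_up",
      "downstream_electrode": "CA3_CA1_t4_dn"
    },
    {
      "tunnel_id": "CA3_CA1_t5",
      "wall": "CA3_CA1",
      "upstream_electrode": "CA3_CA1_t5_up",
      "downstream_electrode": "CA3_CA1_t5_dn"
    },
    {
      "tunnel_id": "CA1_EC_t1",
      "wall": "CA1_EC",
      "upstream_electrode": "CA1_EC_t1_up",
      "downstream_electrode": "CA1_EC_t1_dn"
    },
    {
      "tunnel_id": "CA1_EC_t2",
      "wall": "CA1_EC",
      "upstream_electrode": "CA1_EC_t2_up",
      "downstream_electrode": "CA1_EC_t2_dn"
    },
    {
      "tunnel_id": "CA1_EC_t3",
      "wall": "CA1_EC",
      "upstream_electrode": "CA1_EC_t3_up",
      "downstream_electrode": "CA1_EC_t3_dn"
    },
    {
      "tunnel_id": "CA1_EC_t4",
      "wall": "CA1_EC",
      "upstream_electrode": "CA1_EC_t4_up",
      "downstream_electrode": "CA1_EC_t4_dn"
    },
    {
      "tunnel_id": "CA1_EC_t5",
      "wall": "CA1_EC",
      "upstream_electrode": "CA1_EC_t5_up",
      "downstream_electrode": "CA1_EC_t5_dn"
    }
  ]
}
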