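{
  "format": "perankle-model",
  "version": 1,
  "driver_segment": "tibia",
  "metadata": {
    "name": "synthetic-ankle",
    "generator": "perankle::generate_anatomy",
    "seed": 1,
    "jitter_scale": 0,
    "mortise_width": 0.072,
    "posture_dorsiflexion_deg": 20,
    "name.1": "perankle-reference",
    "calibration": {
      "pipeline": "data-raw/build_reference_model.R",
      "optimizer": "minpack.lm::nls.lm, bounded, staged",
      "objective": 1201.54602231938,
      "converged": false,
      "anchors": {
        "quantity": ["tension", "tension", "plateau_value", "plateau_value", "tension", "plateau_value", "plateau_value", "tension", "pronation", "rise_onset"],
        "ligament": ["TNL", "dATTL", "TSL", "TCL", "TCL", "AITFL", "IOL", "dPTTL", null, "dPTTL"],
        "step": [33, 33, "NA", "NA", 0, "NA", "NA", 33, 33, "NA"],
        "value": [230, 175, 175, 243, 200, 160, 40, 180, 6, 28],
        "achieved": [228.796726467251, 173.892585160669, 182.795791183706, 246.877027222877, 199.65470524433, 163.401903228834, 40.2091795710148, 181.861864595289, 7.22141412808573, 26]
      }
    }
  },
  "segments": [
    {
      "name": "hindfoot",
      "fixed": true
    },
    {
      "name": "tibia",
      "fixed": false
    },
    {
      "name": "talus",
      "fixed": false
    },
    {
      "name": "fibula",
      "fixed": false
    }
  ],
  "joints": [
    {
      "name": "talocrural",
      "parent": "tibia",
      "child": "talus",
      "parent_point": [0, 0, 0],
      "child_point": [0, 0, 0],
      "penalty_stiffness": 10000000,
      "capsule_stiffness": [40, 140, 4],
      "capsule_frame": [
        [1, 0, 0],
        [0, -0.892412776153, 0.451219942999],
        [0, 0.451219942999, 0.892412776153]
      ]
    },
    {
      "name": "subtalar",
      "parent": "talus",
      "child": "hindfoot",
      "parent_point": [0.009192533317, -0.022, -0.007713451316],
      "child_point": [0.009192533317, -0.022, -0.007713451316],
      "penalty_stiffness": 10000000,
      "capsule_stiffness": [120, 120, 500],
      "capsule_frame": [
        [1, 0, 0],
        [0, 1, 0],
        [0, 0, 1]
      ]
    },
    {
      "name": "prox_tibiofibular",
      "parent": "tibia",
      "child": "fibula",
      "parent_point": [-0.011905676075, 0.34, 0.044432588009],
      "child_point": [-0.011905676075, 0.34, 0.044432588009],
      "penalty_stiffness": 10000000,
      "capsule_stiffness": [5, 5, 2],
      "capsule_frame": [
        [1, 0, 0],
        [0, 1, 0],
        [0, 0, 1]
      ]
    }
  ],
  "ligaments": [
    {
      "name": "TNL",
      "origin_segment": "tibia",
      "insertion_segment": "hindfoot",
      "origin_point": [-0.001127924031, -0.006, -0.040013624272],
      "insertion_point": [0.03986830795, -0.018, -0.00876175489],
      "slack_length": 0.0389713450106485,
      "stiffness": 372.644054905708,
      "toe_strain": 0.03,
      "prestrain": -0.0898921688254358
    },
    {
      "name": "TSL",
      "origin_segment": "tibia",
      "insertion_segment": "hindfoot",
      "origin_point": [0.00142501384, -0.008, -0.030071849361],
      "insertion_point": [0.015953044085, -0.025, -0.0082751548],
      "slack_length": 0.0209032135756147,
      "stiffness": 178.770989185193,
      "toe_strain": 0.03,
      "prestrain": 0.0453686428994051
    },
    {
      "name": "TCL",
      "origin_segment": "tibia",
      "insertion_segment": "hindfoot",
      "origin_point": [0.003152589192, -0.01, -0.036192905994],
      "insertion_point": [-0.004601255369, -0.038, -0.011018031729],
      "slack_length": 0.027663946365344,
      "stiffness": 550.924354316594,
      "toe_strain": 0.03,
      "prestrain": 0.0418114487599765
    },
    {
      "name": "dATTL",
      "origin_segment": "tibia",
      "insertion_segment": "talus",
      "origin_point": [-0.002233237466, -0.004, -0.02795673977],
      "insertion_point": [0.017191647992, -0.006, -0.004959107625],
      "slack_length": 0.0174656168143951,
      "stiffness": 156.720370927516,
      "toe_strain": 0.03,
      "prestrain": -0.0329426852691855
    },
    {
      "name": "dPTTL",
      "origin_segment": "tibia",
      "insertion_segment": "talus",
      "origin_point": [-0.004574057198, -0.006505822508, -0.021519247216],
      "insertion_point": [-0.008171828995, -0.014059514178, -0.016038117435],
      "slack_length": 0.00885249882163667,
      "stiffness": 3741.3172926789,
      "toe_strain": 0.03,
      "prestrain": -0.0704366347654107
    },
    {
      "name": "AITFL",
      "origin_segment": "tibia",
      "insertion_segment": "fibula",
      "origin_point": [0.025508477663, 0.006, 0.012402001015],
      "insertion_point": [0.006192101213, -0.004, 0.029677488077],
      "slack_length": 0.0180428169063347,
      "stiffness": 207.935268244743,
      "toe_strain": 0.03,
      "prestrain": 0.19
    },
    {
      "name": "PITFL",
      "origin_segment": "tibia",
      "insertion_segment": "fibula",
      "origin_point": [-0.026898966165, 0.006, 0.031653601697],
      "insertion_point": [0.001602136613, -0.004, 0.041900924949],
      "slack_length": 0.0112263602853666,
      "stiffness": 292.298160669472,
      "toe_strain": 0.03,
      "prestrain": -0.149391311696318
    },
    {
      "name": "IOL_1",
      "origin_segment": "tibia",
      "insertion_segment": "fibula",
      "origin_point": [0.039922833496, 0.03, 0.018377776693],
      "insertion_point": [0.041402555181, 0.026, 0.042750175784],
      "slack_length": 0.00468727373708231,
      "stiffness": 2.8629150012629,
      "toe_strain": 0.03,
      "prestrain": 0.19
    },
    {
      "name": "IOL_2",
      "origin_segment": "tibia",
      "insertion_segment": "fibula",
      "origin_point": [-0.006933532451, 0.07, 0.013168419102],
      "insertion_point": [-0.003813384201, 0.066, 0.027038369699],
      "slack_length": 0.00397035852351083,
      "stiffness": 24.6466212028053,
      "toe_strain": 0.03,
      "prestrain": 0.19
    },
    {
      "name": "IOL_3",
      "origin_segment": "tibia",
      "insertion_segment": "fibula",
      "origin_point": [-0.002438618252, 0.11, 0.018530876458],
      "insertion_point": [2.5227363e-05, 0.106, 0.031208298553],
      "slack_length": 0.00353912432386885,
      "stiffness": 32.0993263722278,
      "toe_strain": 0.03,
      "prestrain": 0.19
    },
    {
      "name": "ATFL",
      "origin_segment": "fibula",
      "insertion_segment": "talus",
      "origin_point": [0.018742017684, -0.014, 0.030446886511],
      "insertion_point": [0.022787278301, -0.006, 0.011780015663],
      "slack_length": 0.00953186234564604,
      "stiffness": 2080.89498096751,
      "toe_strain": 0.03,
      "prestrain": 0.19
    },
    {
      "name": "CFL",
      "origin_segment": "fibula",
      "insertion_segment": "hindfoot",
      "origin_point": [-0.018024978862, -0.018, 0.04587561211],
      "insertion_point": [-0.010288318556, -0.048, 0.03858528623],
      "slack_length": 0.0277089235002119,
      "stiffness": 667.389687399577,
      "toe_strain": 0.03,
      "prestrain": 0.19
    },
    {
      "name": "PTFL",
      "origin_segment": "fibula",
      "insertion_segment": "talus",
      "origin_point": [-0.013996720469, -0.012, 0.030017066348],
      "insertion_point": [-0.011612930278, -0.008, 0.017866463296],
      "slack_length": 0.0192354718222494,
      "stiffness": 24000,
      "toe_strain": 0.03,
      "prestrain": 0.19
    },
    {
      "name": "PTCL",
      "origin_segment": "talus",
      "insertion_segment": "hindfoot",
      "origin_point": [-0.023908672754, -0.012, -0.002091737826],
      "insertion_point": [-0.031980506465, -0.038, -0.001116783894],
      "slack_length": 0.0251323923873555,
      "stiffness": 31.25,
      "toe_strain": 0.03,
      "prestrain": 0.19
    }
  ]
}
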