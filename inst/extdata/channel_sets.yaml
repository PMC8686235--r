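# Nested channel sets for the montage-ablation analysis.
# Only the 63 / 17 / 9 counts are fixed by the study design; the
# intermediate memberships are configurable defaults.
Ch_Set1:
  labels:
  - Fp1
  - Fpz
  - Fp2
  - AF7
  - AF3
  - AFz
  - AF4
  - AF8
  - F7
  - F5
  - F3
  - F1
  - Fz
  - F6
  - F4
  - F2
  - F8
  - FT7
  - FC5
  - FC3
  - FC1
  - FCz
  - FC6
  - FC4
  - FC2
  - FT8
  - T7
  - C5
  - C3
  - C1
  - Cz
  - C2
  - C4
  - C6
  - T8
  - TP9
  - TP7
  - CP5
  - CP3
  - CP1
  - CPz
  - CP6
  - CP4
  - CP2
  - TP8
  - TP10
  - P7
  - P5
  - P3
  - P1
  - Pz
  - P6
  - P4
  - P2
  - P8
  - PO7
  - PO3
  - POz
  - PO4
  - PO8
  - O1
  - Oz
  - O2
Ch_Set2:
  labels:
  - AF3
  - AFz
  - AF4
  - F5
  - F3
  - F1
  - Fz
  - F6
  - F4
  - F2
  - FC5
  - FC3
  - FC1
  - FCz
  - FC6
  - FC4
  - FC2
  - C5
  - C3
  - C1
  - Cz
  - C2
  - C4
  - C6
  - CP5
  - CP3
  - CP1
  - CPz
  - CP6
  - CP4
  - CP2
  - P5
  - P3
  - P1
  - Pz
  - P6
  - P4
  - P2
  - PO3
  - POz
  - PO4
Ch_Set3:
  labels:
  - FC3
  - FC1
  - FCz
  - FC2
  - FC4
  - C5
  - C3
  - C1
  - Cz
  - C2
  - C4
  - C6
  - CP3
  - CP1
  - CPz
  - CP2
  - CP4
  - FC5
  - FC6
  - CP5
  - CP6
  - F5
  - F3
  - F1
  - Fz
  - F2
  - F4
  - F6
  - P5
  - P3
  - P1
  - Pz
  - P2
  - P4
  - P6
Ch_Set4:
  labels:
  - FC3
  - FC1
  - FCz
  - FC2
  - FC4
  - C5
  - C3
  - C1
  - Cz
  - C2
  - C4
  - C6
  - CP3
  - CP1
  - CPz
  - CP2
  - CP4
  per_hand:
    left:
    - FC6
    - FC4
    - FC2
    - FCz
    - FC1
    - C6
    - C4
    - C2
    - Cz
    - C1
    - C3
    - CP6
    - CP4
    - CP2
    - CPz
    - CP1
    - CP3
    right:
    - FC5
    - FC3
    - FC1
    - FCz
    - FC2
    - C5
    - C3
    - C1
    - Cz
    - C2
    - C4
    - CP5
    - CP3
    - CP1
    - CPz
    - CP2
    - CP4
Ch_Set5:
  labels:
  - FC1
  - FC2
  - C1
  - Cz
  - C2
  - C3
  - C4
  - CP1
  - CP2

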