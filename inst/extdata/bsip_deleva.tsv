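name	side	group	proximal_marker	distal_marker	mass_fraction	com_fraction	gyration_fraction
head_trunk	none	head_trunk	head	hip	0.5040	0.5500	0.5200
upper_arm_L	left	upper_limb_L	shoulder_L	elbow_L	0.0271	0.5772	0.2850
upper_arm_R	right	upper_limb_R	shoulder_R	elbow_R	0.0271	0.5772	0.2850
forearm_L	left	upper_limb_L	elbow_L	wrist_L	0.0223	0.5800	0.4300
forearm_R	right	upper_limb_R	elbow_R	wrist_R	0.0223	0.5800	0.4300
thigh_L	left	lower_limb_L	hip	knee_L	0.1416	0.4095	0.3290
thigh_R	right	lower_limb_R	hip	knee_R	0.1416	0.4095	0.3290
shank_L	left	lower_limb_L	knee_L	ankle_L	0.0433	0.4459	0.2550
shank_R	right	lower_limb_R	knee_R	ankle_R	0.0433	0.4459	0.2550
foot_L	left	lower_limb_L	ankle_L	toe_L	0.0137	0.4415	0.2570
foot_R	right	lower_limb_R	ankle_R	toe_R	0.0137	0.4415	0.2570
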