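name	side	group	proximal_marker	distal_marker	mass_fraction	com_fraction	gyration_fraction
head_trunk	none	head_trunk	head	hip	0.578	0.626	0.503
upper_arm_L	left	upper_limb_L	shoulder_L	elbow_L	0.028	0.436	0.322
upper_arm_R	right	upper_limb_R	shoulder_R	elbow_R	0.028	0.436	0.322
forearm_L	left	upper_limb_L	elbow_L	wrist_L	0.022	0.682	0.468
forearm_R	right	upper_limb_R	elbow_R	wrist_R	0.022	0.682	0.468
thigh_L	left	lower_limb_L	hip	knee_L	0.100	0.433	0.323
thigh_R	right	lower_limb_R	hip	knee_R	0.100	0.433	0.323
shank_L	left	lower_limb_L	knee_L	ankle_L	0.0465	0.433	0.302
shank_R	right	lower_limb_R	knee_R	ankle_R	0.0465	0.433	0.302
foot_L	left	lower_limb_L	ankle_L	toe_L	0.0145	0.500	0.475
foot_R	right	lower_limb_R	ankle_R	toe_R	0.0145	0.500	0.475
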