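key	unit	default	description
R20_nm	nm	140	initial droplet radius
sigma2_mN_per_m	mN/m	56	droplet-tissue interfacial tension (14 for lipid-coated)
T0_K	K	310	working temperature
K2_GPa	GPa	2.2	droplet (liquid) bulk modulus
K3_MPa	MPa	0	tissue bulk modulus (alternative to G_MPa)
G_MPa	MPa	-	tissue shear modulus; converted via K3 = 4G/3
Pc_conf_MPa	MPa	0	static confinement pressure added to the resting pressure
f_MHz	MHz	5	drive frequency
tau_divisor	-	10	nucleation window tau = 1/(tau_divisor * f)
include_gas	bool	true	include dissolved-gas partial pressure (O2 + CO2 presets)
include_elastic_barrier	bool	true	apply the confined-barrier (gamma) correction
laplace_factor	-	1	Plap = laplace_factor * sigma2 / R20
Psat_kPa	kPa	135	saturation vapor pressure at T0
roc_mm	mm	60	transducer radius of curvature
aperture_mm	mm	60	transducer aperture diameter
source_pressure_MPa	MPa	0.2	uniform surface pressure amplitude
water_path_mm	mm	30	water standoff before the tissue interface
alpha0_dB_per_cm_MHz	dB/(cm MHz^y)	0.5	tissue attenuation coefficient
alpha_power	-	1	attenuation frequency power y
c0_m_per_s	m/s	1500	sound speed
z_min_mm	mm	10	axial window start
z_max_mm	mm	110	axial window end
dz_mm	mm	0.1	axial grid step
r_max_mm	mm	5	radial half-width
dr_mm	mm	0.1	radial grid step
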