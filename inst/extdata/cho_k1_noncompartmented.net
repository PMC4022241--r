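# Non-compartmented central-metabolism network of CHO-K1 (batch culture).
# 42 reactions over 16 balanced intracellular metabolites: the cytosolic and
# mitochondrial pools of the compartmented model are merged (single pyruvate,
# oxaloacetate, malate, glutamate pool, no channeling pool, no inter-
# compartment transport). Same dialect and conventions as
# cho_k1_compartmented.net; same reconstruction caveats.

name cho_k1_noncompartmented

met GLC_ex 6 extracellular dynamic
met LAC_ex 3 extracellular dynamic
met PYR_ex 3 extracellular dynamic
met ALA_ex 3 extracellular dynamic
met GLU_ex 5 extracellular dynamic
met GLN_ex 5 extracellular dynamic
met ASP_ex 4 extracellular dynamic
met ASN_ex 4 extracellular dynamic
met SER_ex 3 extracellular dynamic
met GLY_ex 2 extracellular dynamic
met AA1_ex 2 extracellular source
met AA2_ex 4 extracellular source
met AA3_ex 5 extracellular source

met G6P 6 cytosolic balanced
met PG 3 cytosolic balanced
met PEP 3 cytosolic balanced
met PYR 3 cytosolic balanced
met LAC 3 cytosolic balanced
met ALA 3 cytosolic balanced
met SER 3 cytosolic balanced
met GLY 2 cytosolic balanced
met ACA 2 cytosolic balanced
met OAA 4 cytosolic balanced
met MAL 4 cytosolic balanced
met CIT 6 cytosolic balanced
met AKG 5 cytosolic balanced
met GLU 5 cytosolic balanced
met GLN 5 cytosolic balanced
met ASP 4 cytosolic balanced

met CO2 1 none co2
met CO2_gas 1 none gas
met C1 1 cytosolic sink
met BM 0 none sink
met FA 0 none sink

rev REV_PYRT hyperbolic rev0=2700 eps=0.01
rev REV_ALAT exponential alpha=0.154 beta=0.0359
rev REV_EMP constant rev=0.5
rev REV_PGM constant rev=1.0
rev REV_LDH constant rev=0.3
rev REV_LACT constant rev=0.05
rev REV_ALATX constant rev=3.0
rev REV_MDH constant rev=2.0
rev REV_IDH constant rev=0.5
rev REV_GDH constant rev=0.5
rev REV_GLNT constant rev=1.0
rev REV_GLUT constant rev=1.0
rev REV_ASPT constant rev=1.0
rev REV_AST constant rev=1.0
rev REV_SERT constant rev=3.0
rev REV_GLYT constant rev=4.6
rev REV_CO2X constant rev=0.3

rxn glc_upt: GLC_ex (abcdef) -> G6P (abcdef)
rxn ppp: G6P (abcdef) + G6P (ghijkl) + G6P (mnopqr) -> PG (def) + PG (jkl) + PG (pqr) + PG (bch) + PG (ino) + CO2 (a) + CO2 (g) + CO2 (m), scale=3, bounds=0:450
rxn emp: G6P (abcdef) -> PG (cba) + PG (def), rev_model=REV_EMP, bounds=0:2000
rxn pgm: PG (abc) -> PEP (abc), rev_model=REV_PGM, bounds=0:2000
rxn pk: PEP (abc) -> PYR (abc)
rxn ldh: PYR (abc) -> LAC (abc), rev_model=REV_LDH
rxn lac_ex: LAC (abc) -> LAC_ex (abc), rev_model=REV_LACT
rxn pyr_ex: PYR (abc) -> PYR_ex (abc), rev_model=REV_PYRT
rxn alat: PYR (abc) + GLU (defgh) -> ALA (abc) + AKG (defgh), rev_model=REV_ALATX
rxn ala_ex: ALA (abc) -> ALA_ex (abc), rev_model=REV_ALAT
rxn pdh: PYR (abc) -> ACA (bc) + CO2 (a)
rxn pc: PYR (abc) + CO2 (d) -> OAA (abcd), bounds=0:300
rxn cs: OAA (abcd) + ACA (ef) -> CIT (abcdef)
rxn idh: CIT (abcdef) -> AKG (abcde) + CO2 (f), rev_model=REV_IDH
rxn tca: AKG (abcde) -> MAL (bcde|edcb) + CO2 (a)
rxn mdh: MAL (abcd) -> OAA (abcd), rev_model=REV_MDH
rxn me: MAL (abcd) -> PYR (abc) + CO2 (d), bounds=0:300
rxn pepck: OAA (abcd) -> PEP (abc) + CO2 (d), bounds=0:400
rxn gdh: GLU (abcde) -> AKG (abcde), rev_model=REV_GDH
rxn gls: GLN (abcde) -> GLU (abcde)
rxn gs: GLU (abcde) -> GLN (abcde), bounds=0:300
rxn gln_upt: GLN_ex (abcde) -> GLN (abcde), rev_model=REV_GLNT
rxn glu_ex: GLU (abcde) -> GLU_ex (abcde), rev_model=REV_GLUT
rxn asp_upt: ASP_ex (abcd) -> ASP (abcd), rev_model=REV_ASPT
rxn asn_upt: ASN_ex (abcd) -> ASP (abcd)
rxn ast: ASP (abcd) + AKG (efghi) -> OAA (abcd) + GLU (efghi), rev_model=REV_AST
rxn ser_upt: SER_ex (abc) -> SER (abc), rev_model=REV_SERT
rxn ser_syn: PG (abc) + GLU (defgh) -> SER (abc) + AKG (defgh)
rxn shmt: SER (abc) -> GLY (ab) + C1 (c)
rxn gly_ex: GLY (ab) -> GLY_ex (ab), rev_model=REV_GLYT
rxn ser_deg: SER (abc) -> PYR (abc), bounds=0:150
rxn aa1_cat: AA1_ex -> ACA (**)
rxn aa2_cat: AA2_ex -> MAL (****)
rxn aa3_cat: AA3_ex -> GLU (*****)
rxn co2_ex: CO2 (a) -> CO2_gas (a), rev_model=REV_CO2X
rxn fas: ACA -> FA
rxn bm_ala: ALA -> BM
rxn bm_asp: ASP -> BM
rxn bm_glu: GLU -> BM
rxn bm_gln: GLN -> BM
rxn bm_gly: GLY -> BM
rxn bm_ser: SER -> BM

measure glc_upt = 371.0
measure lac_ex = 289.4
measure pyr_ex = 3.3
measure ala_ex = 28.7
measure gln_upt = 66.4
measure glu_ex = 15.0
measure asp_upt = 20.1
measure asn_upt = 48.0
measure ser_upt = 48.3
measure gly_ex = 20.0
measure aa1_cat = 92.6
measure aa2_cat = 49.6
measure aa3_cat = 11.6
measure co2_ex = 1817.5
measure fas = 39.1
measure bm_ala = 12.0
measure bm_asp = 15.0
measure bm_glu = 25.0
measure bm_gln = 25.0
measure bm_gly = 10.0
measure bm_ser = 12.0

prefer_free gs pepck me pc ppp
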