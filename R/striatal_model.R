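# The striatal D1R medium-spiny-neuron signaling network.
#
# Two cross-talking axes in one well-mixed volume:
#   calcium axis:  Ca -> calmodulin (two-step loading) -> {CaMKII, PP2B};
#                  CaMKII activation, autophosphorylation, cytosol/PSD
#                  translocation, PSD substrate phosphorylation
#   dopamine axis: DA -> D1R -> Golf -> AC5 -> cAMP (PDE10/PDE4 degraded)
#                  -> PKA -> DARPP-32 Thr-34 (PP1 inhibitor) and Thr-75
#                  (PKA inhibitor, via CDK5), PP2A regulation
#   ARPP-21 (wild type only): PKA phosphorylates Ser-55; phospho-ARPP-21
#                  sequesters Ca2+/calmodulin, competing with CaMKII
#
# All enzymatic steps are explicit binding + catalysis pairs (E+S <-> ES -> E+P);
# there are no Michaelis-Menten or Hill rate laws inside the network.

STRIATAL_VARIANTS <- c("WT", "NO_ARPP21", "D32T34A", "A21S55A", "CAM_OVEREXPRESS")

#' Read the packaged striatal parameter file
#'
#' The file is tab-separated with columns `name`, `value`, `units`,
#' `provenance`; concentrations in uM, time in s. Provenance records whether a
#' value was set from a printed constraint or calibrated against the molecular
#' phenotypes.
#'
#' @param file Path to a parameter TSV; default the packaged file.
#' @return Named numeric vector of parameters (with `provenance` attribute).
#' @export
striatal_parameters <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "striatal_parameters.tsv", package = "msnsig")
  tab <- read.delim(file, stringsAsFactors = FALSE)
  need <- c("name", "value", "units", "provenance")
  if (!all(need %in% names(tab)))
    stop("parameter file must have columns: ", paste(need, collapse = ", "))
  p <- setNames(as.numeric(tab$value), tab$name)
  attr(p, "provenance") <- setNames(tab$provenance, tab$name)
  attr(p, "units") <- setNames(tab$units, tab$name)
  p
}

#' Variant specification
#'
#' @param name One of `"WT"`, `"NO_ARPP21"` (ARPP-21 absent), `"D32T34A"`
#'   (no DARPP-32 Thr-34 phosphorylation), `"A21S55A"` (no ARPP-21 Ser-55
#'   phosphorylation), `"CAM_OVEREXPRESS"` (calmodulin total x3).
#' @param scale_factors Optional named multipliers applied on top of the
#'   variant (parameter -> factor), as in [apply_scaling()].
#' @return A `variant_spec` object.
#' @export
variant_spec <- function(name = "WT", scale_factors = NULL) {
  name <- match.arg(name, STRIATAL_VARIANTS)
  structure(list(name = name, scale_factors = scale_factors),
            class = "variant_spec")
}

# internal: full wild-type reaction set given a parameter vector
striatal_reactions <- function(p) {
  rx <- list()
  add <- function(id, re, pr, kf, kr = 0, kfn = NULL, krn = NULL) {
    rx[[length(rx) + 1L]] <<- reaction(id, re, pr, kf = p[[kf]],
      kr = if (identical(kr, 0)) 0 else p[[kr]],
      kf_name = if (is.null(kfn)) kf else kfn,
      kr_name = if (is.null(krn)) (if (identical(kr, 0)) NULL else kr) else krn)
  }
  ## calcium / calmodulin (sequential loading; negative cooperativity)
  add("cam_ca",  c(CaM = 1, Ca = 1),    c(CaMCa2 = 1), "kf_CaM_Ca",    "kr_CaM_Ca")
  add("cam2_ca", c(CaMCa2 = 1, Ca = 1), c(CaMCa4 = 1), "kf_CaMCa2_Ca", "kr_CaMCa2_Ca")
  ## PP2B (calcineurin): CaM loading at both steps (detailed-balance cycle)
  ## plus a calcium-dependent activation step (regulatory-subunit Ca sites)
  add("pp2b_cam4",    c(PP2B = 1, CaMCa4 = 1),      c(PP2B_CaMCa4 = 1), "kf_PP2B_CaMCa4", "kr_PP2B_CaMCa4")
  add("pp2b_cam2",    c(PP2B = 1, CaMCa2 = 1),      c(PP2B_CaMCa2 = 1), "kf_PP2B_CaMCa2", "kr_PP2B_CaMCa2")
  add("pp2b_cam2_ca", c(PP2B_CaMCa2 = 1, Ca = 1),   c(PP2B_CaMCa4 = 1), "kf_PP2BCaM2_Ca", "kr_PP2BCaM2_Ca")
  add("pp2b_act",     c(PP2B_CaMCa4 = 1, Ca = 1),   c(PP2Ba = 1),       "kf_PP2B_act",    "kr_PP2B_act")
  add("pp2b_d34_bind", c(PP2Ba = 1, D32p34 = 1), c(PP2Ba_D32p34 = 1), "kf_PP2Ba_D32p34", "kr_PP2Ba_D32p34")
  add("pp2b_d34_cat",  c(PP2Ba_D32p34 = 1), c(PP2Ba = 1, D32 = 1),   "kcat_PP2Ba_D32p34")
  ## CaMKII: two pools (cytosol / PSD), CaM-target cycle in each
  for (pool in c("cyt", "psd")) {
    s <- function(base) paste0(base, "_", pool)
    add(s("ck_cam4"),    setNames(c(1, 1), c(s("CK"), "CaMCa4")),     setNames(1, s("CKCaM")),  "kf_CK_CaMCa4", "kr_CK_CaMCa4", "kf_CK_CaMCa4", "kr_CK_CaMCa4")
    add(s("ck_cam2"),    setNames(c(1, 1), c(s("CK"), "CaMCa2")),     setNames(1, s("CKCaM2")), "kf_CK_CaMCa2", "kr_CK_CaMCa2", "kf_CK_CaMCa2", "kr_CK_CaMCa2")
    add(s("ckcam2_ca"),  setNames(c(1, 1), c(s("CKCaM2"), "Ca")),     setNames(1, s("CKCaM")),  "kf_CKCaM2_Ca", "kr_CKCaM2_Ca", "kf_CKCaM2_Ca", "kr_CKCaM2_Ca")
    add(s("ck_auto"),    setNames(2, s("CKCaM")),                     setNames(c(1, 1), c(s("CKpCaM"), s("CKCaM"))), "kcat_CK_auto", 0, "kcat_CK_auto")
    add(s("ck_auto_x"),  setNames(c(1, 1), c(s("CKCaM"), s("CKpCaM"))), setNames(2, s("CKpCaM")), "kcat_CK_auto", 0, "kcat_CK_auto")
    add(s("ckp_cam4"),   setNames(c(1, 1), c(s("CKp"), "CaMCa4")),    setNames(1, s("CKpCaM")), "kf_CKp_CaMCa4", "kr_CKp_CaMCa4", "kf_CKp_CaMCa4", "kr_CKp_CaMCa4")
  }
  ## translocation between F-actin-rich cytosol and PSD
  add("tr_ck",     c(CK_cyt = 1),     c(CK_psd = 1),     "kf_CK_transloc",    "kr_CK_transloc")
  add("tr_ckcam2", c(CKCaM2_cyt = 1), c(CKCaM2_psd = 1), "kf_CK_transloc",    "kr_CK_transloc",    "kf_CK_transloc",    "kr_CK_transloc")
  add("tr_ckcam",  c(CKCaM_cyt = 1),  c(CKCaM_psd = 1),  "kf_CKact_transloc", "kr_CKact_transloc")
  add("tr_ckpcam", c(CKpCaM_cyt = 1), c(CKpCaM_psd = 1), "kf_CKact_transloc", "kr_CKact_transloc", "kf_CKact_transloc", "kr_CKact_transloc")
  add("tr_ckp",    c(CKp_cyt = 1),    c(CKp_psd = 1),    "kf_CKact_transloc", "kr_CKact_transloc", "kf_CKact_transloc", "kr_CKact_transloc")
  ## PSD substrate phosphorylation by the three active PSD CaMKII forms
  add("sub_ckcam_b",  c(CKCaM_psd = 1, Sub = 1),  c(CKCaM_Sub = 1),        "kf_CK_Sub", "kr_CK_Sub")
  add("sub_ckcam_c",  c(CKCaM_Sub = 1),           c(CKCaM_psd = 1, pSub = 1),  "kcat_CK_Sub", 0, "kcat_CK_Sub")
  add("sub_ckpcam_b", c(CKpCaM_psd = 1, Sub = 1), c(CKpCaM_Sub = 1),       "kf_CK_Sub", "kr_CK_Sub", "kf_CK_Sub", "kr_CK_Sub")
  add("sub_ckpcam_c", c(CKpCaM_Sub = 1),          c(CKpCaM_psd = 1, pSub = 1), "kcat_CK_Sub", 0, "kcat_CK_Sub")
  add("sub_ckp_b",    c(CKp_psd = 1, Sub = 1),    c(CKp_Sub = 1),          "kf_CK_Sub", "kr_CK_Sub", "kf_CK_Sub", "kr_CK_Sub")
  add("sub_ckp_c",    c(CKp_Sub = 1),             c(CKp_psd = 1, pSub = 1),    "kcat_CK_Sub", 0, "kcat_CK_Sub")
  ## PP1: substrate and CaMKII dephosphorylation, inhibition by p34-DARPP-32
  add("pp1_psub_b", c(PP1 = 1, pSub = 1),    c(PP1_pSub = 1),      "kf_PP1_pSub", "kr_PP1_pSub")
  add("pp1_psub_c", c(PP1_pSub = 1),         c(PP1 = 1, Sub = 1),  "kcat_PP1_pSub")
  add("pp1_ckp_b",  c(PP1 = 1, CKp_psd = 1), c(PP1_CKp = 1),       "kf_PP1_CKp", "kr_PP1_CKp")
  add("pp1_ckp_c",  c(PP1_CKp = 1),          c(PP1 = 1, CK_psd = 1), "kcat_PP1_CKp")
  add("pp1_d34",    c(PP1 = 1, D32p34 = 1),  c(PP1_D32p34 = 1),    "kf_PP1_D32p34", "kr_PP1_D32p34")
  ## dopamine receptor / G protein / AC5 / cAMP
  add("d1r_da",    c(DA = 1, D1R = 1),     c(D1R_DA = 1),          "kf_DA_D1R", "kr_DA_D1R")
  add("golf_act",  c(D1R_DA = 1, Golf = 1), c(D1R_DA = 1, Golf_a = 1), "kcat_D1R_Golf")
  add("golf_gtp",  c(Golf_a = 1),          c(Golf = 1),            "k_Golf_decay")
  add("ac5_golf",  c(AC5 = 1, Golf_a = 1), c(AC5_Golf = 1),        "kf_AC5_Golf", "kr_AC5_Golf")
  add("ac5_basal", c(AC5 = 1),             c(AC5 = 1, cAMP = 1),   "kcat_AC5_basal")
  add("ac5_stim",  c(AC5_Golf = 1),        c(AC5_Golf = 1, cAMP = 1), "kcat_AC5_Golf")
  add("pde10_b",   c(PDE10 = 1, cAMP = 1), c(PDE10_cAMP = 1),      "kf_PDE10_cAMP", "kr_PDE10_cAMP")
  add("pde10_c",   c(PDE10_cAMP = 1),      c(PDE10 = 1),           "kcat_PDE10_cAMP")
  add("pde4_b",    c(PDE4 = 1, cAMP = 1),  c(PDE4_cAMP = 1),       "kf_PDE4_cAMP", "kr_PDE4_cAMP")
  add("pde4_c",    c(PDE4_cAMP = 1),       c(PDE4 = 1),            "kcat_PDE4_cAMP")
  ## PKA holoenzyme: two cooperative cAMP-binding steps, catalytic release
  add("pka_camp1", c(PKA = 1, cAMP = 2),   c(PKAc2 = 1),           "kf_PKA_cAMP",  "kr_PKA_cAMP")
  add("pka_camp2", c(PKAc2 = 1, cAMP = 2), c(PKAc4 = 1),           "kf_PKAc2_cAMP", "kr_PKAc2_cAMP")
  add("pka_diss1", c(PKAc4 = 1),           c(PKAr1 = 1, PKAc = 1), "kf_PKA_diss",  "kr_PKA_diss")
  add("pka_diss2", c(PKAr1 = 1),           c(PKAr = 1, PKAc = 1),  "kf_PKA_diss2", "kr_PKA_diss2")
  ## DARPP-32
  add("d32_pka_b", c(PKAc = 1, D32 = 1),   c(PKAc_D32 = 1),        "kf_PKAc_D32", "kr_PKAc_D32")
  add("d32_pka_c", c(PKAc_D32 = 1),        c(PKAc = 1, D32p34 = 1), "kcat_PKAc_D32")
  add("d32_cdk5_b", c(CDK5 = 1, D32 = 1),  c(CDK5_D32 = 1),        "kf_CDK5_D32", "kr_CDK5_D32")
  add("d32_cdk5_c", c(CDK5_D32 = 1),       c(CDK5 = 1, D32p75 = 1), "kcat_CDK5_D32")
  add("pka_p75",   c(PKAc = 1, D32p75 = 1), c(PKAc_D32p75 = 1),    "kf_PKAc_D32p75", "kr_PKAc_D32p75")
  ## PP2A: basal, PKA-phosphorylated and calcium-bound forms
  add("pp2a_pka_b", c(PKAc = 1, PP2A = 1), c(PKAc_PP2A = 1),       "kf_PKAc_PP2A", "kr_PKAc_PP2A")
  add("pp2a_pka_c", c(PKAc_PP2A = 1),      c(PKAc = 1, PP2Ap = 1), "kcat_PKAc_PP2A")
  add("pp2ap_off",  c(PP2Ap = 1),          c(PP2A = 1),            "k_PP2Ap_decay")
  add("pp2a_ca",    c(PP2A = 1, Ca = 1),   c(PP2ACa = 1),          "kf_PP2A_Ca", "kr_PP2A_Ca")
  add("p75_pp2a_b",   c(PP2A = 1, D32p75 = 1),   c(PP2A_D32p75 = 1),   "kf_PP2A_D32p75", "kr_PP2A_D32p75")
  add("p75_pp2a_c",   c(PP2A_D32p75 = 1),        c(PP2A = 1, D32 = 1), "kcat_PP2A_D32p75")
  add("p75_pp2ap_b",  c(PP2Ap = 1, D32p75 = 1),  c(PP2Ap_D32p75 = 1),  "kf_PP2A_D32p75", "kr_PP2A_D32p75", "kf_PP2A_D32p75", "kr_PP2A_D32p75")
  add("p75_pp2ap_c",  c(PP2Ap_D32p75 = 1),       c(PP2Ap = 1, D32 = 1), "kcat_PP2Ap_D32p75")
  add("p75_pp2aca_b", c(PP2ACa = 1, D32p75 = 1), c(PP2ACa_D32p75 = 1), "kf_PP2A_D32p75", "kr_PP2A_D32p75", "kf_PP2A_D32p75", "kr_PP2A_D32p75")
  add("p75_pp2aca_c", c(PP2ACa_D32p75 = 1),      c(PP2ACa = 1, D32 = 1), "kcat_PP2ACa_D32p75")
  add("p34_pp2a_b",   c(PP2A = 1, D32p34 = 1),   c(PP2A_D32p34 = 1),   "kf_PP2A_D32p34", "kr_PP2A_D32p34")
  add("p34_pp2a_c",   c(PP2A_D32p34 = 1),        c(PP2A = 1, D32 = 1), "kcat_PP2A_D32p34")
  add("p34_pp2aca_b", c(PP2ACa = 1, D32p34 = 1), c(PP2ACa_D32p34 = 1), "kf_PP2A_D32p34", "kr_PP2A_D32p34", "kf_PP2A_D32p34", "kr_PP2A_D32p34")
  add("p34_pp2aca_c", c(PP2ACa_D32p34 = 1),      c(PP2ACa = 1, D32 = 1), "kcat_PP2ACa_D32p34")
  add("p34_pp2ap_b",  c(PP2Ap = 1, D32p34 = 1),  c(PP2Ap_D32p34 = 1),  "kf_PP2A_D32p34", "kr_PP2A_D32p34", "kf_PP2A_D32p34", "kr_PP2A_D32p34")
  add("p34_pp2ap_c",  c(PP2Ap_D32p34 = 1),       c(PP2Ap = 1, D32 = 1), "kcat_PP2Ap_D32p34")
  ## PKA-activity reporter (AKAR-like): phosphorylated by free PKA catalytic
  ## subunit, dephosphorylated by PP1; a tracer pool that does not load the
  ## network
  add("akar_pka_b", c(PKAc = 1, AKAR = 1),  c(PKAc_AKAR = 1),        "kf_PKAc_AKAR", "kr_PKAc_AKAR")
  add("akar_pka_c", c(PKAc_AKAR = 1),       c(PKAc = 1, pAKAR = 1),  "kcat_PKAc_AKAR")
  add("akar_pp1_b", c(PP1 = 1, pAKAR = 1),  c(PP1_pAKAR = 1),        "kf_PP1_pAKAR", "kr_PP1_pAKAR")
  add("akar_pp1_c", c(PP1_pAKAR = 1),       c(PP1 = 1, AKAR = 1),    "kcat_PP1_pAKAR")
  ## ARPP-21 (wild type only; removed in NO_ARPP21)
  add("a21_pka_b",  c(PKAc = 1, A21 = 1),     c(PKAc_A21 = 1),         "kf_PKAc_A21", "kr_PKAc_A21")
  add("a21_pka_c",  c(PKAc_A21 = 1),          c(PKAc = 1, A21p55 = 1), "kcat_PKAc_A21")
  add("a21_pp2a_b", c(PP2A = 1, A21p55 = 1),  c(PP2A_A21p55 = 1),      "kf_PP2A_A21p55", "kr_PP2A_A21p55")
  add("a21_pp2a_c", c(PP2A_A21p55 = 1),       c(PP2A = 1, A21 = 1),    "kcat_PP2A_A21p55")
  add("a21_pp2ap_b", c(PP2Ap = 1, A21p55 = 1), c(PP2Ap_A21p55 = 1),    "kf_PP2A_A21p55", "kr_PP2A_A21p55", "kf_PP2A_A21p55", "kr_PP2A_A21p55")
  add("a21_pp2ap_c", c(PP2Ap_A21p55 = 1),      c(PP2Ap = 1, A21 = 1),  "kcat_PP2Ap_A21p55")
  add("a21_cam4",   c(A21p55 = 1, CaMCa4 = 1), c(A21p55_CaMCa4 = 1),   "kf_A21p55_CaMCa4", "kr_A21p55_CaMCa4")
  add("a21_cam2",   c(A21p55 = 1, CaMCa2 = 1), c(A21p55_CaMCa2 = 1),   "kf_A21p55_CaMCa2", "kr_A21p55_CaMCa2")
  add("a21cam2_ca", c(A21p55_CaMCa2 = 1, Ca = 1), c(A21p55_CaMCa4 = 1), "kf_A21CaM2_Ca", "kr_A21CaM2_Ca")
  rx
}

# internal: species table for the wild-type network; basal inputs and cAMP
# seed value; everything else starts in the moiety base species (the basal
# state is located by steady_state before any experiment)
striatal_species <- function(p) {
  sp <- list(
    species_def("Ca", "input", 0.060, clamped = TRUE),
    species_def("DA", "input", 0.020, clamped = TRUE),
    species_def("CaM", initial = p[["TA_CaM"]]), species_def("CaMCa2"), species_def("CaMCa4"),
    species_def("PP2B", initial = p[["TA_PP2B"]]), species_def("PP2B_CaMCa2"),
    species_def("PP2B_CaMCa4"), species_def("PP2Ba"), species_def("PP2Ba_D32p34"),
    species_def("CK_cyt", initial = p[["TA_CaMKII"]]), species_def("CK_psd", "PSD"),
    species_def("CKCaM2_cyt"), species_def("CKCaM2_psd", "PSD"),
    species_def("CKCaM_cyt"), species_def("CKCaM_psd", "PSD"),
    species_def("CKpCaM_cyt"), species_def("CKpCaM_psd", "PSD"),
    species_def("CKp_cyt"), species_def("CKp_psd", "PSD"),
    species_def("Sub", "PSD", p[["TA_Sub"]]), species_def("pSub", "PSD"),
    species_def("CKCaM_Sub", "PSD"), species_def("CKpCaM_Sub", "PSD"),
    species_def("CKp_Sub", "PSD"),
    species_def("PP1", "PSD", p[["TA_PP1"]]), species_def("PP1_pSub", "PSD"),
    species_def("PP1_CKp", "PSD"), species_def("PP1_D32p34", "PSD"),
    species_def("D1R", initial = p[["TA_D1R"]]), species_def("D1R_DA"),
    species_def("Golf", initial = p[["TA_Golf"]]), species_def("Golf_a"),
    species_def("AC5", initial = p[["TA_AC5"]]), species_def("AC5_Golf"),
    species_def("cAMP", initial = 0.06),
    species_def("PDE10", initial = p[["TA_PDE10"]]), species_def("PDE10_cAMP"),
    species_def("PDE4", initial = p[["TA_PDE4"]]), species_def("PDE4_cAMP"),
    species_def("PKA", initial = p[["TA_PKA"]]), species_def("PKAc2"),
    species_def("PKAc4"), species_def("PKAr1"), species_def("PKAr"), species_def("PKAc"),
    species_def("PKAc_D32p75"),
    species_def("D32", initial = p[["TA_DARPP32"]]), species_def("D32p34"),
    species_def("D32p75"), species_def("PKAc_D32"),
    species_def("CDK5", initial = p[["TA_CDK5"]]), species_def("CDK5_D32"),
    species_def("PP2A", initial = p[["TA_PP2A"]]), species_def("PP2Ap"),
    species_def("PP2ACa"), species_def("PKAc_PP2A"),
    species_def("PP2A_D32p75"), species_def("PP2Ap_D32p75"), species_def("PP2ACa_D32p75"),
    species_def("PP2A_D32p34"), species_def("PP2ACa_D32p34"),
    species_def("PP2Ap_D32p34"), species_def("PP2Ap_A21p55"),
    species_def("AKAR", "PSD", p[["TA_AKAR"]]), species_def("pAKAR", "PSD"),
    species_def("PKAc_AKAR", "PSD"), species_def("PP1_pAKAR", "PSD"),
    species_def("A21", initial = p[["TA_ARPP21"]]), species_def("A21p55"),
    species_def("PKAc_A21"), species_def("PP2A_A21p55"),
    species_def("A21p55_CaMCa2"), species_def("A21p55_CaMCa4")
  )
  sp
}

# internal: conserved moieties (weights = copies of the core per complex).
# `scan = FALSE` marks bookkeeping duplicates excluded from TA_ parameters.
striatal_moieties <- function(p) {
  m <- list(
    CaM = list(members = c(CaM = 1, CaMCa2 = 1, CaMCa4 = 1, PP2B_CaMCa2 = 1,
                           PP2B_CaMCa4 = 1, PP2Ba = 1, PP2Ba_D32p34 = 1,
                           CKCaM2_cyt = 1, CKCaM2_psd = 1, CKCaM_cyt = 1,
                           CKCaM_psd = 1, CKpCaM_cyt = 1, CKpCaM_psd = 1,
                           CKCaM_Sub = 1, CKpCaM_Sub = 1,
                           A21p55_CaMCa2 = 1, A21p55_CaMCa4 = 1),
               total = p[["TA_CaM"]]),
    CaMKII = list(members = c(CK_cyt = 1, CK_psd = 1, CKCaM2_cyt = 1, CKCaM2_psd = 1,
                              CKCaM_cyt = 1, CKCaM_psd = 1, CKpCaM_cyt = 1,
                              CKpCaM_psd = 1, CKp_cyt = 1, CKp_psd = 1,
                              CKCaM_Sub = 1, CKpCaM_Sub = 1, CKp_Sub = 1,
                              PP1_CKp = 1),
                  total = p[["TA_CaMKII"]]),
    PP2B = list(members = c(PP2B = 1, PP2B_CaMCa2 = 1, PP2B_CaMCa4 = 1,
                            PP2Ba = 1, PP2Ba_D32p34 = 1), total = p[["TA_PP2B"]]),
    PP1 = list(members = c(PP1 = 1, PP1_pSub = 1, PP1_CKp = 1, PP1_D32p34 = 1,
                           PP1_pAKAR = 1),
               total = p[["TA_PP1"]]),
    Substrate = list(members = c(Sub = 1, pSub = 1, CKCaM_Sub = 1, CKpCaM_Sub = 1,
                                 CKp_Sub = 1, PP1_pSub = 1), total = p[["TA_Sub"]]),
    D1R = list(members = c(D1R = 1, D1R_DA = 1), total = p[["TA_D1R"]]),
    Golf = list(members = c(Golf = 1, Golf_a = 1, AC5_Golf = 1), total = p[["TA_Golf"]]),
    AC5 = list(members = c(AC5 = 1, AC5_Golf = 1), total = p[["TA_AC5"]], scan = FALSE),
    PDE10 = list(members = c(PDE10 = 1, PDE10_cAMP = 1), total = p[["TA_PDE10"]]),
    PDE4 = list(members = c(PDE4 = 1, PDE4_cAMP = 1), total = p[["TA_PDE4"]]),
    PKA = list(members = c(PKA = 1, PKAc2 = 1, PKAc4 = 1, PKAr1 = 1, PKAr = 1),
               total = p[["TA_PKA"]]),
    PKA_C = list(members = c(PKA = 2, PKAc2 = 2, PKAc4 = 2, PKAr1 = 1, PKAc = 1,
                             PKAc_D32 = 1, PKAc_A21 = 1, PKAc_PP2A = 1,
                             PKAc_D32p75 = 1, PKAc_AKAR = 1),
                 total = 2 * p[["TA_PKA"]], scan = FALSE),
    DARPP32 = list(members = c(D32 = 1, D32p34 = 1, D32p75 = 1, PKAc_D32 = 1,
                               CDK5_D32 = 1, PP2Ba_D32p34 = 1, PP1_D32p34 = 1,
                               PKAc_D32p75 = 1, PP2A_D32p75 = 1, PP2Ap_D32p75 = 1,
                               PP2ACa_D32p75 = 1, PP2A_D32p34 = 1, PP2ACa_D32p34 = 1,
                               PP2Ap_D32p34 = 1),
                   total = p[["TA_DARPP32"]]),
    CDK5 = list(members = c(CDK5 = 1, CDK5_D32 = 1), total = p[["TA_CDK5"]]),
    AKAR = list(members = c(AKAR = 1, pAKAR = 1, PKAc_AKAR = 1, PP1_pAKAR = 1),
                total = p[["TA_AKAR"]]),
    PP2A = list(members = c(PP2A = 1, PP2Ap = 1, PP2ACa = 1, PKAc_PP2A = 1,
                            PP2A_D32p75 = 1, PP2Ap_D32p75 = 1, PP2ACa_D32p75 = 1,
                            PP2A_D32p34 = 1, PP2ACa_D32p34 = 1, PP2Ap_D32p34 = 1,
                            PP2A_A21p55 = 1, PP2Ap_A21p55 = 1),
                total = p[["TA_PP2A"]]),
    ARPP21 = list(members = c(A21 = 1, A21p55 = 1, PKAc_A21 = 1, PP2A_A21p55 = 1,
                              PP2Ap_A21p55 = 1, A21p55_CaMCa2 = 1, A21p55_CaMCa4 = 1),
                  total = p[["TA_ARPP21"]])
  )
  m
}

# internal: detailed-balance cycles declared for the packaged model
striatal_cycles <- function() {
  list(
    calmodulin_CaMKII = list(ids = c("cam2_ca", "ck_cam4_cyt", "ckcam2_ca_cyt", "ck_cam2_cyt"),
                             dirs = c(1, 1, -1, -1)),
    calmodulin_PP2B   = list(ids = c("cam2_ca", "pp2b_cam4", "pp2b_cam2_ca", "pp2b_cam2"),
                             dirs = c(1, 1, -1, -1)),
    calmodulin_ARPP21 = list(ids = c("cam2_ca", "a21_cam4", "a21cam2_ca", "a21_cam2"),
                             dirs = c(1, 1, -1, -1))
  )
}

#' Observable read-outs of the striatal model
#'
#' Each observable is a fixed sum (coefficients 0/1) over species:
#' `active_CaMKII` (all Ca2+/calmodulin-bound and autophosphorylated forms,
#' both pools, including substrate-engaged complexes), `active_PP1` (PP1 not
#' bound to Thr-34-phospho-DARPP-32), `pSubstrate`, `pDARPP32_T34`,
#' `pDARPP32_T75`, `pARPP21_S55`, `cAMP`, `available_CaMCa4` (free fully
#' loaded calmodulin), `pARPP21_CaMCa4_complex`, `active_Golf`, `active_PKA`.
#'
#' @param model A striatal [build_model()] result.
#' @return Named list of species-name character vectors.
#' @export
striatal_observables <- function(model) {
  obs <- list(
    active_CaMKII = c("CKCaM_cyt", "CKCaM_psd", "CKpCaM_cyt", "CKpCaM_psd",
                      "CKp_cyt", "CKp_psd", "CKCaM_Sub", "CKpCaM_Sub", "CKp_Sub"),
    active_PP1 = c("PP1", "PP1_pSub", "PP1_CKp"),
    pSubstrate = c("pSub", "PP1_pSub"),
    pDARPP32_T34 = c("D32p34", "PP1_D32p34", "PP2Ba_D32p34", "PP2A_D32p34",
                     "PP2ACa_D32p34", "PP2Ap_D32p34"),
    pDARPP32_T75 = c("D32p75", "PKAc_D32p75", "PP2A_D32p75", "PP2Ap_D32p75",
                     "PP2ACa_D32p75"),
    pARPP21_S55 = c("A21p55", "A21p55_CaMCa2", "A21p55_CaMCa4", "PP2A_A21p55",
                    "PP2Ap_A21p55"),
    cAMP = "cAMP",
    pAKAR = c("pAKAR", "PP1_pAKAR"),
    available_CaMCa4 = "CaMCa4",
    pARPP21_CaMCa4_complex = "A21p55_CaMCa4",
    active_Golf = c("Golf_a", "AC5_Golf"),
    active_PKA = c("PKAc", "PKAc_D32", "PKAc_A21", "PKAc_PP2A")
  )
  present <- model$species$name
  lapply(obs, function(v) intersect(v, present))
}

#' Evaluate an observable on a simulation result
#'
#' @param result A [simulate()] result of a striatal model.
#' @param model The model the result came from.
#' @param name Observable name (see [striatal_observables()]).
#' @return Numeric vector over the output time grid (uM).
#' @export
observable <- function(result, model, name) {
  obs <- striatal_observables(model)
  if (!name %in% names(obs)) stop("unknown observable '", name, "'")
  sp <- obs[[name]]
  if (!length(sp)) return(rep(0, length(result$time)))
  rowSums(result$concentrations[, sp, drop = FALSE])
}

#' Build the striatal signaling network
#'
#' Assembles the full wild-type network from the packaged parameter file and
#' applies the requested variant: `NO_ARPP21` removes all ARPP-21 species and
#' reactions; `D32T34A` removes the PKA-catalyzed Thr-34 phosphorylation of
#' DARPP-32; `A21S55A` removes the PKA-catalyzed Ser-55 phosphorylation of
#' ARPP-21; `CAM_OVEREXPRESS` triples total calmodulin.
#'
#' @param variant A [variant_spec()] or a variant name.
#' @param params Optional parameter vector (default the packaged file, see
#'   [striatal_parameters()]).
#' @return A [network_model()] with the variant name in attribute `variant`.
#' @export
build_model <- function(variant = "WT", params = NULL) {
  if (is.character(variant)) variant <- variant_spec(variant)
  stopifnot(inherits(variant, "variant_spec"))
  p <- if (is.null(params)) striatal_parameters() else params
  need <- striatal_parameter_names()
  miss <- setdiff(need, names(p))
  if (length(miss))
    stop("parameter file is missing: ", paste(miss, collapse = ", "))
  sp <- striatal_species(p)
  rx <- striatal_reactions(p)
  mo <- striatal_moieties(p)
  cy <- striatal_cycles()
  drop_species <- character(0)
  drop_rx <- character(0)
  if (variant$name == "NO_ARPP21") {
    drop_species <- c("A21", "A21p55", "PKAc_A21", "PP2A_A21p55",
                      "PP2Ap_A21p55", "A21p55_CaMCa2", "A21p55_CaMCa4")
    mo$ARPP21 <- NULL
    mo$CaM$members <- mo$CaM$members[setdiff(names(mo$CaM$members), drop_species)]
    mo$PP2A$members <- mo$PP2A$members[setdiff(names(mo$PP2A$members), drop_species)]
    mo$PKA_C$members <- mo$PKA_C$members[setdiff(names(mo$PKA_C$members), drop_species)]
    cy$calmodulin_ARPP21 <- NULL
  } else if (variant$name == "D32T34A") {
    drop_rx <- c("d32_pka_b", "d32_pka_c")
    drop_species <- "PKAc_D32"
    mo$DARPP32$members <- mo$DARPP32$members[names(mo$DARPP32$members) != "PKAc_D32"]
    mo$PKA_C$members <- mo$PKA_C$members[names(mo$PKA_C$members) != "PKAc_D32"]
  } else if (variant$name == "A21S55A") {
    drop_rx <- c("a21_pka_b", "a21_pka_c")
    drop_species <- "PKAc_A21"
    mo$ARPP21$members <- mo$ARPP21$members[names(mo$ARPP21$members) != "PKAc_A21"]
    mo$PKA_C$members <- mo$PKA_C$members[names(mo$PKA_C$members) != "PKAc_A21"]
  }
  if (length(drop_species)) {
    sp <- Filter(function(s) !s$name %in% drop_species, sp)
    rx <- Filter(function(r) !any(c(names(r$reactants), names(r$products))
                                  %in% drop_species), rx)
  }
  if (length(drop_rx))
    rx <- Filter(function(r) !r$id %in% drop_rx, rx)
  prov <- attr(p, "provenance")
  m <- network_model(sp, rx, moieties = mo, cycles = cy,
                     provenance = if (is.null(prov)) NULL else
                       data.frame(parameter = names(prov), source = unname(prov)))
  if (variant$name == "CAM_OVEREXPRESS")
    m <- apply_scaling(m, c(TA_CaM = 3))
  if (!is.null(variant$scale_factors))
    m <- apply_scaling(m, variant$scale_factors)
  attr(m, "variant") <- variant$name
  m
}

#' Names of all parameters of the striatal model
#' @return Character vector.
#' @export
striatal_parameter_names <- function() {
  c("TA_CaM", "TA_PP2B", "TA_CaMKII", "TA_Sub", "TA_PP1", "TA_D1R", "TA_Golf",
    "TA_AC5", "TA_PDE10", "TA_PDE4", "TA_PKA", "TA_DARPP32", "TA_CDK5",
    "TA_PP2A", "TA_ARPP21",
    "kf_CaM_Ca", "kr_CaM_Ca", "kf_CaMCa2_Ca", "kr_CaMCa2_Ca",
    "kf_PP2B_CaMCa4", "kr_PP2B_CaMCa4", "kf_PP2B_CaMCa2", "kr_PP2B_CaMCa2",
    "kf_PP2BCaM2_Ca", "kr_PP2BCaM2_Ca", "kf_PP2B_act", "kr_PP2B_act",
    "kf_PP2Ba_D32p34", "kr_PP2Ba_D32p34", "kcat_PP2Ba_D32p34",
    "kf_CK_CaMCa4", "kr_CK_CaMCa4", "kf_CK_CaMCa2", "kr_CK_CaMCa2",
    "kf_CKCaM2_Ca", "kr_CKCaM2_Ca", "kcat_CK_auto",
    "kf_CKp_CaMCa4", "kr_CKp_CaMCa4",
    "kf_CK_transloc", "kr_CK_transloc", "kf_CKact_transloc", "kr_CKact_transloc",
    "kf_CK_Sub", "kr_CK_Sub", "kcat_CK_Sub",
    "kf_PP1_pSub", "kr_PP1_pSub", "kcat_PP1_pSub",
    "kf_PP1_CKp", "kr_PP1_CKp", "kcat_PP1_CKp",
    "kf_PP1_D32p34", "kr_PP1_D32p34",
    "kf_DA_D1R", "kr_DA_D1R", "kcat_D1R_Golf", "k_Golf_decay",
    "kf_AC5_Golf", "kr_AC5_Golf", "kcat_AC5_basal", "kcat_AC5_Golf",
    "kf_PDE10_cAMP", "kr_PDE10_cAMP", "kcat_PDE10_cAMP",
    "kf_PDE4_cAMP", "kr_PDE4_cAMP", "kcat_PDE4_cAMP",
    "kf_PKA_cAMP", "kr_PKA_cAMP", "kf_PKAc2_cAMP", "kr_PKAc2_cAMP",
    "kf_PKA_diss", "kr_PKA_diss", "kf_PKA_diss2", "kr_PKA_diss2",
    "kf_PKAc_D32", "kr_PKAc_D32", "kcat_PKAc_D32",
    "kf_CDK5_D32", "kr_CDK5_D32", "kcat_CDK5_D32",
    "kf_PKAc_D32p75", "kr_PKAc_D32p75",
    "kf_PKAc_PP2A", "kr_PKAc_PP2A", "kcat_PKAc_PP2A", "k_PP2Ap_decay",
    "kf_PP2A_Ca", "kr_PP2A_Ca",
    "kf_PP2A_D32p75", "kr_PP2A_D32p75", "kcat_PP2A_D32p75",
    "kcat_PP2Ap_D32p75", "kcat_PP2ACa_D32p75",
    "kf_PP2A_D32p34", "kr_PP2A_D32p34", "kcat_PP2A_D32p34", "kcat_PP2ACa_D32p34",
    "kcat_PP2Ap_D32p34",
    "TA_AKAR", "kf_PKAc_AKAR", "kr_PKAc_AKAR", "kcat_PKAc_AKAR",
    "kf_PP1_pAKAR", "kr_PP1_pAKAR", "kcat_PP1_pAKAR",
    "kf_PKAc_A21", "kr_PKAc_A21", "kcat_PKAc_A21",
    "kf_PP2A_A21p55", "kr_PP2A_A21p55", "kcat_PP2A_A21p55", "kcat_PP2Ap_A21p55",
    "kf_A21p55_CaMCa4", "kr_A21p55_CaMCa4",
    "kf_A21p55_CaMCa2", "kr_A21p55_CaMCa2",
    "kf_A21CaM2_Ca", "kr_A21CaM2_Ca")
}

# internal: direct parameter overrides (including zero) used by treatments
# such as PDE10 inhibition or synthesis-off; unlike apply_scaling this sets
# absolute values.
set_parameters <- function(model, values) {
  for (pn in names(values)) {
    hit <- FALSE
    for (ri in seq_along(model$reactions)) {
      rx <- model$reactions[[ri]]
      if (identical(rx$kf_name, pn)) { model$reactions[[ri]]$kf <- values[[pn]]; hit <- TRUE }
      if (rx$kr > 0 && identical(rx$kr_name, pn)) { model$reactions[[ri]]$kr <- values[[pn]]; hit <- TRUE }
    }
    if (!hit) stop("unknown rate parameter '", pn, "'")
  }
  model
}
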