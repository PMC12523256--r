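# Shared fixtures: record builders and the independent staging oracle.

nm <- function() missing_value("not_mentioned")

# Compact record builder: staging fields by value, everything else missing
# unless given.
make_record <- function(report_id = "R1", patient_id = "P1",
                        t = nm(), n = nm(), m = nm(),
                        primary = nm(), secondary = nm(), tertiary = nm(),
                        pct_secondary = nm(), gg = nm(),
                        psa = nm(), epe = nm(), svi = nm(), pni = nm(),
                        histology = nm(), margins = nm(),
                        nodes_examined = nm(), nodes_mets = nm()) {
  pathology_record(
    patient_id = patient_id, report_id = report_id,
    t_stage = t, n_stage = n, m_stage = m,
    gleason = gleason_info(primary = primary, secondary = secondary,
                           tertiary = tertiary,
                           pct_secondary = pct_secondary,
                           reported_grade_group = gg),
    psa_ng_ml = psa, epe = epe, svi = svi, perineural_invasion = pni,
    histologic_subtype = histology, resection_margins = margins,
    nodes_examined = nodes_examined, nodes_with_metastasis = nodes_mets)
}

# Independent brute-force oracle of the AJCC 8e prostate prognostic stage
# groups, written as nested group definitions (deliberately a different
# structure from the engine's prioritized rule scan). Complete inputs only.
T_CODES_ALL <- c("T1", "T1a", "T1b", "T1c", "T2", "T2a", "T2b", "T2c",
                 "T3", "T3a", "T3b", "T4")
ajcc_oracle <- function(t, n, m, gg, psa) {
  t12a <- c("T1", "T1a", "T1b", "T1c", "T2", "T2a")
  t34 <- c("T3", "T3a", "T3b", "T4")
  if (m == "M1") return("IVB")
  if (n == "N1") return("IVA")
  if (gg == 5) return("IIIC")
  if (t %in% t34) return("IIIB")
  if (psa >= 20) return("IIIA")
  if (gg == 2) return("IIB")
  if (gg %in% c(3, 4)) return("IIC")
  # GG1, PSA < 20
  if (t %in% t12a && psa < 10) return("I")
  "IIA"
}

# independent hand-written ISUP 2014 lookup (pattern pair -> group)
isup_lookup <- local({
  keys <- c("3+3", "3+4", "3+5", "4+3", "4+4", "4+5", "5+3", "5+4", "5+5")
  vals <- c(1L, 2L, 4L, 3L, 4L, 5L, 4L, 5L, 5L)
  stats::setNames(vals, keys)
})

stage_of <- function(...) stage_label(stage_record(make_record(...)))
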