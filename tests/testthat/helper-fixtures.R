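# Small fixtures built in code; no files on disk.

# one-sample congener table with chosen concentrations (others absent)
tiny_table <- function(conc, date = as.Date("2015-01-12"), city = "HZ",
                       sample_id = "s1") {
  congener_table(tibble::tibble(
    sample_id = sample_id, city = city, date = date,
    congener = names(conc), conc_ng_m3 = unname(conc)
  ))
}

# adult stratum with controllable degeneracy; defaults are all point values
# so simulations reduce to scalar arithmetic unless a spec is passed in
point_group <- function(ir = 10, et = 24, bw = 60, ed = 70, ef = 365,
                        at_hours = 70 * 365 * 24, cf = 1e-9, csf = 3.14,
                        age_group = "adult", gender = "total") {
  population_group(
    city = "HZ", age_group = age_group, gender = gender,
    ir = ir, et = et, bw = bw, ed = ed, ef = ef,
    at_hours = at_hours, cf = cf, csf = csf
  )
}

# deterministic scalar ILCR for all-point inputs (independent of the package
# simulation path: single-line arithmetic from the risk formula)
scalar_ilcr <- function(teq_ng, ir = 10, cf = 1e-9, ed = 70, et = 24,
                        ef = 365, csf = 3.14, bw = 60,
                        at_hours = 70 * 365 * 24) {
  (teq_ng * 1000 * ir * cf * ed * et * ef) * csf / (bw * at_hours)
}
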