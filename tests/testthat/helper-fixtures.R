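# Shared fixtures built in code.

hcb <- function() as_compound("HCB")
pecb <- function() as_compound("PeCB")

# noise-free PRC panel generated from the forward retention model
make_prc_panel <- function(beta, log_ksw = c(3.5, 4.0, 4.5, 5.0),
                           duration = 91, sampler_mass = 0.030) {
  tibble::tibble(
    log_ksw = log_ksw,
    fraction = prc_fraction(beta, log_ksw, duration, sampler_mass)
  )
}

# minimal Cw table for ratio/benchmark tests
make_cw_table <- function(ratios, site_ids = NULL) {
  n <- length(ratios)
  if (is.null(site_ids)) site_ids <- sprintf("s%02d", seq_len(n))
  tibble::tibble(
    site_id = rep(site_ids, each = 2),
    deployment_id = rep(sprintf("d%02d", seq_len(n)), each = 2),
    matrix = "freshwater",
    compound = rep(c("HCB", "PeCB"), n),
    c_w = as.vector(rbind(ratios, 1)),
    censored = FALSE
  )
}
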