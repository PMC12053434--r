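# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) assign(name, force(expr), envir = .fixtures)
  get(name, envir = .fixtures)
}

# small paired cohort used across modules
tiny_config <- function(seed = 11, ...) {
  sim_config(
    n_subjects = 20, n_sites = 3000, seed = seed,
    ...
  )
}

tiny_cohort <- function() {
  fixture("tiny_cohort", {
    cfg <- tiny_config()
    panel <- simulate_reference_panel(cfg)
    simulate_survival(simulate_cohort(cfg, panel))
  })
}

tiny_panel <- function() tiny_cohort()$panel

# metadata tibble for hand-built cases
toy_metadata <- function(n = 6) {
  tibble::tibble(
    subject_id = sprintf("T%02d", seq_len(n)),
    sample_id = sprintf("T%02d_s1", seq_len(n)),
    age = seq(30, by = 5, length.out = n),
    sex = rep(c("M", "F"), length.out = n),
    cmv = rep(c("positive", "negative"), length.out = n),
    transplant = rep(c("pre", "post"), length.out = n),
    atg = rep(c("yes", "no"), length.out = n),
    infection_risk = rep(c("no", "yes"), length.out = n),
    ancestry_pc1 = seq_len(n) / n
  )
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

.rdirichlet_test <- function(n, alpha) {
  g <- matrix(rgamma(n * length(alpha), shape = alpha), nrow = n, byrow = TRUE)
  g / rowSums(g)
}

write_tsv_text <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
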