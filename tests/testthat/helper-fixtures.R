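# in-code fixtures shared across test files

make_tows <- function(n = 3, habitat = "littoral",
                      date = as.Date("2014-06-24"),
                      diameter = 0.75, speed = 0.6, duration = 120,
                      n_nets = 2L, dry_mass = 10, larval_count = 0L) {
  tibble::tibble(
    tow_id = sprintf("t%02d", seq_len(n)),
    habitat = habitat, date = date,
    net_diameter_m = diameter, speed_m_s = speed, duration_s = duration,
    n_nets = n_nets, dry_mass_mg = dry_mass,
    larval_count = as.integer(larval_count)
  )
}

make_reference <- function(taxon, habitat, d13C, d15N = 5, CN = 4.2) {
  n <- max(lengths(list(taxon, habitat, d13C, d15N, CN)))
  tibble::tibble(
    sample_id = sprintf("r%03d", seq_len(n)),
    taxon = rep_len(taxon, n), habitat = rep_len(habitat, n),
    date = as.Date("2014-06-15"),
    d13C_bulk = rep_len(d13C, n), d15N = rep_len(d15N, n),
    CN_bulk = rep_len(CN, n), pooled_n = 1L
  )
}

# balanced reference draws: one taxon's samples split across habitats
draw_reference <- function(n_per_habitat, means_d13C, means_d15N,
                           sd_d13C = 0.8, sd_d15N = 0.6, CN = 4.2) {
  rows <- lapply(names(means_d13C), function(tx) {
    lapply(c("littoral", "shoreline", "pelagic"), function(h) {
      make_reference(tx, h,
                     d13C = rnorm(n_per_habitat, means_d13C[[tx]], sd_d13C),
                     d15N = rnorm(n_per_habitat, means_d15N[[tx]], sd_d15N),
                     CN = CN)
    })
  })
  out <- dplyr::bind_rows(rows)
  out$sample_id <- sprintf("r%04d", seq_len(nrow(out)))
  out
}

make_fish <- function(habitat, sl, mass, month = "September",
                      stage = "juvenile") {
  n <- max(lengths(list(habitat, sl, mass)))
  d <- tibble::tibble(
    fish_id = sprintf("f%03d", seq_len(n)),
    habitat = rep_len(habitat, n),
    date = as.Date(sprintf("2014-%02d-15",
                           match(month, c("June", "July", "August", "September")) + 5L)),
    stage = stage,
    standard_length_mm = rep_len(sl, n),
    wet_mass_g = rep_len(mass, n),
    age0 = TRUE
  )
  d$month <- factor(month, levels = c("June", "July", "August", "September"))
  d
}
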