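# Fixture builders shared across the suite. Everything is generated in code;
# no binary fixtures are stored.

# A mask with `n_in` in-set voxels filled in array order.
block_mask <- function(n_in, dim = c(10, 10, 2), spacing = c(1, 1, 1),
                       offset = 0) {
  v <- array(FALSE, dim)
  if (n_in > 0) v[offset + seq_len(n_in)] <- TRUE
  label_mask(v, spacing)
}

# A solid ball of given radius (voxels) centred in the grid.
ball_mask <- function(radius, dim = c(24, 24, 24), spacing = c(1, 1, 1),
                      centre = (dim + 1) / 2) {
  co <- lapply(1:3, function(ax) (seq_len(dim[ax]) - centre[ax]) * spacing[ax])
  d2 <- outer(outer(co[[1]]^2, co[[2]]^2, `+`), co[[3]]^2, `+`)
  label_mask(d2 <= radius^2, spacing)
}

# A random mask with approximately `p` occupancy.
random_mask <- function(dim = c(8, 8, 4), p = 0.3, spacing = c(1, 1, 1)) {
  label_mask(array(stats::runif(prod(dim)) < p, dim), spacing)
}

# A tiny in-memory cohort: `n_femurs` femurs x 4 records, built from one
# reference ball per femur with simple deterministic perturbations.
tiny_cohort <- function(n_femurs = 3, dim = c(16, 16, 8), spacing = c(1, 1, 2)) {
  types <- rep(c("osteolytic", "osteoblastic", "mixed"), length.out = n_femurs)
  rows <- list()
  for (i in seq_len(n_femurs)) {
    base <- ball_mask(3 + (i %% 3), dim = dim, spacing = spacing,
                      centre = c(8, 8, 4))
    for (op in c("I", "II")) for (se in c("1", "2")) {
      v <- base$voxels
      # shift operator II by one voxel, session 2 by one more
      sh <- (op == "II") + (se == "2")
      if (sh > 0) {
        v2 <- array(FALSE, dim(v))
        v2[(1 + sh):dim(v)[1], , ] <- v[1:(dim(v)[1] - sh), , ]
        v <- v2
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        femur_id = sprintf("T%02d", i), operator = op, session = se,
        lesion_type = types[i], mask_path = NA_character_,
        mask = list(label_mask(v, spacing)), complete = TRUE
      )
    }
  }
  dplyr::bind_rows(rows)
}

# Write a cohort with masks in memory to NIfTI files + manifest in `dir`.
write_tiny_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cohort$mask_path <- sprintf("%s_%s_%s.nii.gz", cohort$femur_id,
                              cohort$operator, cohort$session)
  for (i in seq_len(nrow(cohort))) {
    write_mask(cohort$mask[[i]], file.path(dir, cohort$mask_path[i]))
  }
  write_manifest(cohort, file.path(dir, "manifest.csv"))
  file.path(dir, "manifest.csv")
}

# Brute-force Dice and non-overlap from raw logical arrays (the independent
# oracle for the overlap metrics).
oracle_dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
oracle_non_overlap <- function(a, b, spacing) {
  (sum(a) + sum(b) - 2 * sum(a & b)) * prod(spacing) / 1000
}

# Independent Kruskal-Wallis oracle: rank formula with tie correction.
oracle_kruskal <- function(values, groups) {
  r <- rank(values)
  n <- length(values)
  groups <- as.factor(groups)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, function(x) sum(x)^2 / length(x))) - 3 * (n + 1)
  ties <- table(values)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h <- h / correction
  list(statistic = h, p.value = stats::pchisq(h, nlevels(groups) - 1,
                                              lower.tail = FALSE))
}
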