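# shared fixture builders and independent oracles

tiny_layout <- function(plate_id = "P1", n_compounds = 12, n_dmso = 2, n_eact = 2,
                        format = 384) {
  screen_layout(plate_id, sprintf("C%03d", seq_len(n_compounds)),
                format = format, n_dmso = n_dmso, n_eact = n_eact)
}

# a bare tracks table for fit_swell
make_track <- function(frame, area, track_id = 1, plate_id = "P1", well = "A01") {
  data.frame(track_id = track_id, plate_id = plate_id, well = well,
             frame = frame, x = 0, y = 0, area = area)
}

# all permutations of 1..n (n small)
perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, matrix(setdiff(seq_len(n), k)[sub], nrow(sub)))))
}

# brute-force minimum-cost one-to-one matching over all complete permutations
# (all pairs admissible); returns per-row matched column
bf_perm_match <- function(d) {
  p <- perms(ncol(d))
  costs <- apply(p, 1L, function(pp) sum(d[cbind(seq_len(nrow(d)), pp)]))
  p[which.min(costs), ]
}

# brute-force minimum-cost partial matching with gating: each row may take an
# unused admissible column or stay unmatched at cost `nomatch` (each unmatched
# column also costs `nomatch`); mirrors the linker's objective
bf_partial_match <- function(d, ok, nomatch) {
  nt <- nrow(d); no <- ncol(d)
  best <- list(cost = Inf, match = rep(NA_integer_, nt))
  recurse <- function(i, used, match, cost) {
    if (cost >= best$cost) return()
    if (i > nt) {
      cost <- cost + (no - sum(used)) * nomatch
      if (cost < best$cost) best <<- list(cost = cost, match = match)
      return()
    }
    for (j in which(ok[i, ] & !used)) {
      match[i] <- j
      recurse(i + 1L, replace(used, j, TRUE), match, cost + d[i, j])
    }
    match[i] <- NA_integer_
    recurse(i + 1L, used, match, cost + nomatch)
  }
  recurse(1L, rep(FALSE, no), rep(NA_integer_, nt), 0)
  best$match
}

# canonical signature of a track partition: set of observation keys per track,
# independent of labels and input order
partition_signature <- function(tracks) {
  key <- paste(tracks$plate_id, tracks$well, tracks$frame, tracks$x, tracks$y, tracks$area)
  sort(vapply(split(key, tracks$track_id),
              function(k) paste(sort(k), collapse = " | "), character(1)))
}

md5_of_dir <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  setNames(as.character(tools::md5sum(files)), basename(files))
}
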