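# Shared builders for small in-code fixtures.

mkCommunity <- function(m, plots = sprintf("p%d", seq_len(nrow(m))),
                        species = sprintf("s%d", seq_len(ncol(m)))) {
  dimnames(m) <- list(plots, species)
  CommunityMatrix(m)
}

mkTraits <- function(m, species = sprintf("s%d", seq_len(nrow(m))),
                     traitNames = sprintf("t%d", seq_len(ncol(m)))) {
  dimnames(m) <- list(species, traitNames)
  TraitTable(m)
}

mkFunctions <- function(m, plots = sprintf("p%d", seq_len(nrow(m))),
                        funcs = sprintf("F%d", seq_len(ncol(m)))) {
  dimnames(m) <- list(plots, funcs)
  FunctionMatrix(m)
}

# Function matrix engineered so the per-plot count of functions above the
# threshold is constant (8) below t = 55, rises exactly linearly 0..8 over
# the diversity gradient 1..9 at t = 55, and collapses above it. With
# k = 1 the per-function maximum is exactly 1.
linearCountFixture <- function() {
  nf <- 8L
  v <- matrix(0.54, 9, nf)
  for (p in 2:8) if (p - 1 >= 1) v[p, seq_len(p - 1)] <- 0.55
  v[9, ] <- 1.0
  fm <- mkFunctions(v)
  list(functions = fm, diversity = stats::setNames(as.numeric(1:9),
                                                   rownames(v)),
       tStar = 55L, nFuncs = nf)
}

# Independent hull-volume oracle: qhull through scipy. `cases` is a list of
# point matrices (1-3 columns); returns one volume per case, NA for
# degenerate hulls.
hullOracleVolumes <- function(cases) {
  rows <- lapply(seq_along(cases), function(i) {
    p <- cases[[i]]
    data.frame(case = i, x1 = p[, 1],
               x2 = if (ncol(p) >= 2) p[, 2] else NA,
               x3 = if (ncol(p) >= 3) p[, 3] else NA)
  })
  csv <- tempfile(fileext = ".csv")
  utils::write.csv(do.call(rbind, rows), csv, row.names = FALSE, na = "")
  script <- test_path("hull_oracle.py")
  out <- system2("python", c(shQuote(script), shQuote(csv)), stdout = TRUE)
  parts <- strsplit(out, ",", fixed = TRUE)
  ids <- as.integer(vapply(parts, `[`, "", 1))
  vols <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2)))
  vols[order(ids)]
}

# Path of the installed command-line front end.
emfCliPath <- function() {
  path <- system.file("exec", "emf", package = "bemf")
  if (!nzchar(path)) path <- file.path(find.package("bemf"), "exec", "emf")
  path
}

runEmf <- function(...) {
  args <- c(emfCliPath(), ...)
  res <- suppressWarnings(system2("Rscript", shQuote(args), stdout = TRUE,
                                  stderr = TRUE))
  status <- attr(res, "status")
  list(output = res, status = if (is.null(status)) 0L else status)
}
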