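# Independent brute-force oracles used to cross-check the package's
# implementations. Written as plain loops, deliberately naive.

# -- event classification oracle: rules (fusion / fission / translocation /
#    complex) applied literally to a units-by-colors count matrix; returns a
#    sorted vector of "type:color,color" signatures.
oracle_classify <- function(M, params = event_params()) {
  min_g <- params$min_genes; mf <- params$major_frac
  sf <- params$split_frac; hf <- params$home_frac
  M[M > 0 & M < min_g] <- 0
  nu <- nrow(M); nc <- ncol(M)
  cols <- colnames(M)
  rowsum <- rep(0, nu); colsum <- rep(0, nc)
  for (u in seq_len(nu)) for (c in seq_len(nc)) {
    rowsum[u] <- rowsum[u] + M[u, c]
    colsum[c] <- colsum[c] + M[u, c]
  }
  majors <- vector("list", nu)
  for (u in seq_len(nu)) {
    ms <- integer(0)
    for (c in seq_len(nc))
      if (M[u, c] >= min_g && rowsum[u] > 0 && M[u, c] / rowsum[u] >= mf)
        ms <- c(ms, c)
    majors[[u]] <- ms
  }
  strong <- vector("list", nc)   # fission carriers per color
  fiss <- integer(0)
  for (c in seq_len(nc)) {
    cars <- integer(0)
    for (u in seq_len(nu))
      if (M[u, c] >= min_g && colsum[c] > 0 && M[u, c] / colsum[c] >= sf)
        cars <- c(cars, u)
    strong[[c]] <- cars
    if (length(cars) >= 2) fiss <- c(fiss, c)
  }
  # complex seeds
  seeds <- list()
  for (u in seq_len(nu))
    if (length(majors[[u]]) >= 3)
      seeds[[length(seeds) + 1]] <- list(units = u, colors = majors[[u]])
  for (c in fiss) {
    fus_with <- integer(0)
    for (u in seq_len(nu))
      if (c %in% majors[[u]] && length(majors[[u]]) >= 2)
        fus_with <- c(fus_with, u)
    if (length(fus_with)) {
      invol <- integer(0)
      for (u in fus_with) invol <- union(invol, majors[[u]])
      seeds[[length(seeds) + 1]] <-
        list(units = union(fus_with, strong[[c]]),
             colors = union(c, invol))
    }
  }
  # transitive merge
  repeat {
    merged_any <- FALSE
    if (length(seeds) >= 2) {
      for (i in seq_len(length(seeds) - 1)) {
        for (j in seq(i + 1, length(seeds))) {
          if (length(intersect(seeds[[i]]$units, seeds[[j]]$units)) ||
              length(intersect(seeds[[i]]$colors, seeds[[j]]$colors))) {
            seeds[[i]]$units <- union(seeds[[i]]$units, seeds[[j]]$units)
            seeds[[i]]$colors <- union(seeds[[i]]$colors, seeds[[j]]$colors)
            seeds[[j]] <- NULL
            merged_any <- TRUE
            break
          }
        }
        if (merged_any) break
      }
    }
    if (!merged_any) break
  }
  cx_units <- integer(0); cx_colors <- integer(0)
  for (s in seeds) {
    cx_units <- union(cx_units, s$units)
    cx_colors <- union(cx_colors, s$colors)
  }
  sig <- character(0)
  for (s in seeds)
    sig <- c(sig, paste0("complex:", paste(sort(cols[s$colors]),
                                           collapse = ",")))
  for (u in seq_len(nu)) {
    if (u %in% cx_units) next
    ms <- majors[[u]]
    if (length(ms) == 2)
      sig <- c(sig, paste0("fusion:", paste(sort(cols[ms]), collapse = ",")))
  }
  for (c in fiss)
    if (!c %in% cx_colors)
      sig <- c(sig, paste0("fission:", cols[c]))
  # translocations
  for (c in seq_len(nc)) {
    if (colsum[c] == 0) next
    home <- which.max(M[, c])
    if (M[home, c] / colsum[c] < hf) next
    for (u in seq_len(nu)) {
      if (u == home) next
      if (M[u, c] < min_g) next
      if (rowsum[u] == 0 || M[u, c] / rowsum[u] >= mf) next
      mc <- which.max(M[u, ])
      if (mc == c) next
      sig <- c(sig, paste0("translocation:",
                           paste(sort(cols[c(c, mc)]), collapse = ",")))
    }
  }
  sort(sig)
}

event_sigs <- function(ev) sort(ev$signature)

# -- run-length segmentation oracle (uncolored NA entries are transparent)
oracle_runs <- function(colors) {
  colors <- colors[!is.na(colors)]
  if (!length(colors)) return(data.frame(color = character(0),
                                         gene_count = integer(0)))
  vals <- character(0); lens <- integer(0)
  for (x in colors) {
    n <- length(vals)
    if (n && vals[n] == x) lens[n] <- lens[n] + 1L
    else { vals <- c(vals, x); lens <- c(lens, 1L) }
  }
  data.frame(color = vals, gene_count = lens, stringsAsFactors = FALSE)
}

# -- greedy maximum-cosine pairing oracle
oracle_greedy_units <- function(M) {
  cos <- function(a, b) {
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0) return(0)
    sum(a * b) / (na * nb)
  }
  avail <- seq_len(nrow(M))
  units <- list()
  while (length(avail) >= 2) {
    best <- c(NA, NA); bs <- -Inf
    for (i in seq_along(avail)) for (j in seq_along(avail)) {
      if (j <= i) next
      s <- cos(M[avail[i], ], M[avail[j], ])
      if (s > bs) { bs <- s; best <- c(avail[i], avail[j]) }
    }
    if (bs < 0.2) break
    units[[length(units) + 1]] <- best
    avail <- setdiff(avail, best)
  }
  for (a in avail) units[[length(units) + 1]] <- a
  units
}

# small painted karyotype straight from vectors of per-chromosome colors
toy_karyotype <- function(..., species = "toy", ploidy = 1L) {
  chroms <- list(...)
  if (is.null(names(chroms)))
    names(chroms) <- paste0("chr", seq_along(chroms))
  rows <- lapply(names(chroms), function(ch) {
    cols <- chroms[[ch]]
    n <- length(cols)
    data.frame(chromosome = ch, start = (seq_len(n) - 1L) * 100L,
               end = (seq_len(n) - 1L) * 100L + 50L,
               gene_id = paste0(ch, "_g", seq_len(n)),
               color = cols, stringsAsFactors = FALSE)
  })
  painted_karyotype(do.call(rbind, rows), species = species, ploidy = ploidy)
}
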