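# Independent brute-force oracles. These deliberately re-derive results from
# first principles (regex matching; explicit pairwise loops over the
# hydrogen-bond energy and turn/bridge rules) and share no scanning or
# assignment code with the package.

# --- motif oracle: overlapping regex matching --------------------------------

oracle_scan <- function(sequence, pattern_source) {
  # bracket notation is already valid regex; lookahead captures overlaps
  rx <- paste0("(?=(", pattern_source, "))")
  m <- gregexpr(rx, sequence, perl = TRUE)[[1]]
  if (m[1] == -1) return(integer(0))
  as.integer(m)
}

# --- secondary-structure oracle ---------------------------------------------

# plain-loop Kabsch-Sander re-implementation over the backbone of one chain
oracle_ss_chain <- function(bb) {
  n <- length(bb$resno)
  lab <- rep("C", n)
  if (n < 3) return(lab)
  seg <- integer(n); seg[1] <- 1L
  if (n > 1) for (i in 2:n) {
    gap <- any(!is.finite(bb$CA[i - 1, ])) || any(!is.finite(bb$CA[i, ])) ||
      sqrt(sum((bb$CA[i, ] - bb$CA[i - 1, ])^2)) > 4.5
    seg[i] <- seg[i - 1] + as.integer(gap)
  }
  H <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    if (i == 1 || bb$code1[i] == "P" || seg[i] != seg[i - 1]) next
    co <- bb$C[i - 1, ] - bb$O[i - 1, ]
    if (any(!is.finite(co)) || any(!is.finite(bb$N[i, ]))) next
    H[i, ] <- bb$N[i, ] + 1.01 * co / sqrt(sum(co^2))
  }
  dd <- function(a, b) sqrt(sum((a - b)^2))
  bond <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (abs(i - j) < 2 || seg[i] != seg[j]) next
    if (any(!is.finite(H[i, ])) || any(!is.finite(bb$N[i, ])) ||
        any(!is.finite(bb$C[j, ])) || any(!is.finite(bb$O[j, ]))) next
    e <- 0.084 * 332 * (1 / dd(bb$O[j, ], bb$N[i, ]) +
                        1 / dd(bb$C[j, ], H[i, ]) -
                        1 / dd(bb$O[j, ], H[i, ]) -
                        1 / dd(bb$C[j, ], bb$N[i, ]))
    bond[i, j] <- e < -0.5
  }
  hb <- function(a, b) a >= 1 && b >= 1 && a <= n && b <= n && bond[a, b]
  turn <- array(FALSE, c(3, n))  # rows: 3-, 4-, 5-turn at i
  for (k in 3:5) for (i in seq_len(max(n - k, 0)))
    if (bond[i + k, i]) turn[k - 2, i] <- TRUE
  # turn interiors -> T
  for (k in 3:5) for (i in which(turn[k - 2, ]))
    for (j in (i + 1):(i + k - 1)) if (j <= n && lab[j] == "C") lab[j] <- "T"
  # bridges
  bridged <- rep(FALSE, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j - i < 3) next
    par <- (hb(i - 1, j) && hb(j, i + 1)) || (hb(j - 1, i) && hb(i, j + 1))
    anti <- (hb(i, j) && hb(j, i)) || (hb(i - 1, j + 1) && hb(j - 1, i + 1))
    if (par || anti) { bridged[i] <- TRUE; bridged[j] <- TRUE }
  }
  for (i in which(bridged)) {
    lad <- (i > 1 && bridged[i - 1]) || (i < n && bridged[i + 1])
    lab[i] <- if (lad) "E" else "B"
  }
  # helices, weakest to strongest so 4-turn helices win
  for (k in c(5, 3, 4)) {
    sym <- c(`3` = "G", `4` = "H", `5` = "I")[[as.character(k)]]
    for (i in 2:n) if (turn[k - 2, i] && turn[k - 2, i - 1])
      for (j in i:min(i + k - 1, n)) lab[j] <- sym
  }
  # simplify to 3 classes
  out <- c(H = "H", G = "H", I = "H", E = "E", B = "E", T = "C", C = "C")[lab]
  unname(out)
}

oracle_ss <- function(model, chain = chain_ids(model)[1]) {
  oracle_ss_chain(backbone_coords(model, chain))
}

# random amino-acid sequence over the 20 standard letters
random_seq <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}
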