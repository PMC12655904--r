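# random descriptor table with controllable correlation, for oracle checks
randomTable <- function(n, p, seed = 1, corr = 0) {
  set.seed(seed)
  Z <- matrix(rnorm(n * p), n, p)
  if (corr != 0 && p >= 2)
    Z[, 2] <- corr * Z[, 1] + sqrt(1 - corr^2) * Z[, 2]
  colnames(Z) <- sprintf("D%02d", seq_len(p))
  DescriptorTable(Z)
}

# brute-force OLS via the normal equations
oracleOls <- function(X, y) {
  D <- cbind(1, X)
  solve(t(D) %*% D, t(D) %*% y)[, 1]
}

# brute-force hat-matrix diagonal
oracleLeverage <- function(X) {
  D <- cbind(1, X)
  unname(diag(D %*% solve(t(D) %*% D) %*% t(D)))
}

# brute-force all-pairs ligand/residue contact scan
oracleContacts <- function(complex, cutoff) {
  a <- complex@atoms
  lig <- a[a$ligand, ]
  rec <- a[!a$ligand, ]
  keys <- unique(paste(rec$chain, rec$resno, rec$resname, sep = "|"))
  hits <- vapply(keys, function(k) {
    sub <- rec[paste(rec$chain, rec$resno, rec$resname, sep = "|") == k, ]
    dmin <- Inf
    for (i in seq_len(nrow(sub)))
      for (j in seq_len(nrow(lig)))
        dmin <- min(dmin, sqrt(sum((c(sub$x[i], sub$y[i], sub$z[i]) -
                                    c(lig$x[j], lig$y[j], lig$z[j]))^2)))
    dmin <= cutoff
  }, logical(1))
  sort(as.integer(vapply(strsplit(keys[hits], "|", fixed = TRUE),
                         `[`, character(1), 2)))
}
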