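# Independent oracles: exhaustive / enumeration / hand-computation
# counterparts of the package's operations. These stay deliberately naive.

# exhaustive O(n^2) within-radius counts
bruteCounts <- function(ref, target, r, torus = FALSE, W = NULL, H = NULL) {
  vapply(seq_len(nrow(ref)), function(i) {
    dx <- abs(ref$x_um[i] - target$x_um)
    dy <- abs(ref$y_um[i] - target$y_um)
    if (torus) {
      dx <- pmin(dx, W - dx)
      dy <- pmin(dy, H - dy)
    }
    d <- sqrt(dx^2 + dy^2)
    same <- if (!is.null(ref$cell_id) && !is.null(target$cell_id))
      target$cell_id == ref$cell_id[i] else rep(FALSE, nrow(target))
    sum(d <= r & !same)
  }, numeric(1))
}

# literal double-sum K estimator
bruteK <- function(xr, yr, idr, xt, yt, idt, r, W, H,
                   normalization, correction) {
  s <- 0
  for (i in seq_along(xr)) {
    for (j in seq_along(xt)) {
      if (!is.null(idr) && idr[i] == idt[j]) next
      dx <- abs(xr[i] - xt[j]); dy <- abs(yr[i] - yt[j])
      if (sqrt(dx^2 + dy^2) <= r) {
        e <- if (correction == "translation")
          (W * H) / ((W - dx) * (H - dy)) else 1
        s <- s + e
      }
    }
  }
  D <- if (normalization == "as_printed")
    length(xr) * (length(xr) - 1) else length(xr) * length(xt)
  W * H * s / D
}

# exact two-sided Mann-Whitney p by full enumeration of group labelings
enumMannWhitneyP <- function(x, y) {
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  nx <- length(x)
  idx <- utils::combn(length(pooled), nx)
  ustat <- function(xs, ys) sum(outer(xs, ys, ">"))
  u0 <- ustat(x, y)
  us <- apply(idx, 2, function(ii) ustat(pooled[ii], pooled[-ii]))
  min(1, 2 * min(mean(us <= u0), mean(us >= u0)))
}

# exact two-sided signed-rank p by enumeration of all sign assignments
enumSignedRankP <- function(pre, post) {
  d <- post - pre
  d <- d[d != 0]
  stopifnot(!anyDuplicated(abs(d)))
  rk <- rank(abs(d))
  v0 <- sum(rk[d > 0])
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.vector(signs %*% rk)
  min(1, 2 * min(mean(vs <= v0), mean(vs >= v0)))
}

# two-sided Spearman p by full permutation of one ranking
enumSpearmanP <- function(x, y) {
  r0 <- abs(cor(x, y, method = "spearman"))
  rx <- rank(x)
  perms <- permuteAll(rank(y))
  rs <- apply(perms, 1, function(p) abs(cor(rx, p, method = "pearson")))
  mean(rs >= r0 - 1e-12)
}

permuteAll <- function(v) {
  n <- length(v)
  if (n == 1) return(matrix(v, 1))
  out <- NULL
  for (i in seq_len(n))
    out <- rbind(out, cbind(v[i], permuteAll(v[-i])))
  out
}

# Type II sums of squares by explicit least-squares model comparisons
# (QR on hand-built model matrices; no anova helpers)
orableTypeII <- function(y, A, B) {
  A <- factor(A); B <- factor(B)
  rss <- function(X) {
    q <- qr(X)
    sum(qr.resid(q, y)^2)
  }
  mm <- function(form) model.matrix(form, data.frame(A = A, B = B))
  rssA_B <- rss(mm(~A + B))
  rssA <- rss(mm(~A))
  rssB <- rss(mm(~B))
  rssFull <- rss(mm(~A * B))
  dfe <- length(y) - nlevels(A) * nlevels(B)
  mse <- rssFull / dfe
  dfA <- nlevels(A) - 1; dfB <- nlevels(B) - 1; dfAB <- dfA * dfB
  list(FA = ((rssB - rssA_B) / dfA) / mse,
       FB = ((rssA - rssA_B) / dfB) / mse,
       FAB = ((rssA_B - rssFull) / dfAB) / mse,
       dfe = dfe)
}

# hand product-limit estimator (no censoring handling needed beyond risk set)
oracleKM <- function(times, events) {
  tev <- sort(unique(times[events]))
  s <- 1
  surv <- numeric(length(tev))
  for (k in seq_along(tev)) {
    atRisk <- sum(times >= tev[k])
    d <- sum(times == tev[k] & events)
    s <- s * (1 - d / atRisk)
    surv[k] <- s
  }
  data.frame(time = tev, survival = surv)
}

# build a TILField from explicit marker rows
makeField <- function(x, y, markers, width = 100, height = 100,
                      id = "f1") {
  n <- length(x)
  df <- data.frame(cell_id = as.character(seq_len(n)), x_um = x, y_um = y)
  for (m in tilMarkers()) df[[m]] <- rep(FALSE, n)
  df$DAPI <- TRUE
  for (m in names(markers)) df[[m]][markers[[m]]] <- TRUE
  assignPhenotypes(TILField(id, width, height, df))
}

# random field with two phenotype populations for oracle-equivalence loops
randomTwoTypeField <- function(n1, n2, width = 200, height = 150) {
  makeField(runif(n1 + n2, 0, width), runif(n1 + n2, 0, height),
            list(CD4 = seq_len(n1), CD8 = n1 + seq_len(n2)),
            width, height)
}
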