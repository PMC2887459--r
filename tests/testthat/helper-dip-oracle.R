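# Independent oracle for the dip statistic: exact minimisation of the
# sup-norm distance to a unimodal CDF by linear programming, with the
# mode searched over data points, gap midpoints and both tails.  The LP
# is solved by a small dense two-phase simplex written here, fully
# independent of the package's modal-interval algorithm.

solve_lp <- function(cvec, A, b) {
  # variables z free -> z = zp - zm ; standard form with slacks; minimize
  nv <- length(cvec); nc <- nrow(A)
  A2 <- cbind(A, -A, diag(nc))      # zp, zm, s
  c2 <- c(cvec, -cvec, rep(0, nc))
  # ensure b >= 0 rows
  neg <- b < 0
  A2[neg, ] <- -A2[neg, ]
  b2 <- abs(b)
  eqsign <- ifelse(neg, -1, 1)      # rows flipped became >= ; slack sign wrong -> use artificials
  # Build phase-1 with artificials for flipped rows (slack coefficient -1 there)
  for (i in which(neg)) A2[i, 2*nv + i] <- -1
  nA <- ncol(A2)
  art <- which(neg)
  if (length(art)) {
    Aart <- matrix(0, nc, length(art)); for (k in seq_along(art)) Aart[art[k], k] <- 1
    T1 <- cbind(A2, Aart)
  } else T1 <- A2
  basis <- integer(nc)
  basis[!neg] <- 2*nv + which(!neg)
  if (length(art)) basis[neg] <- nA + seq_along(art)
  simplex_core <- function(Tm, b2, basis, cost) {
    iter <- 0
    repeat {
      iter <- iter + 1
      if (iter > 5000) return(NULL)  # degenerate cycling guard
      cb <- cost[basis]
      # reduced costs
      y <- tryCatch(solve(t(Tm[, basis, drop=FALSE]), cb), error=function(e) NULL)
      if (is.null(y)) return(NULL)
      rc <- cost - as.vector(t(Tm) %*% y)
      enter <- which(rc < -1e-11)
      if (!length(enter)) return(list(basis=basis, xb=solve(Tm[, basis, drop=FALSE], b2)))
      e <- enter[1]  # Bland
      d <- solve(Tm[, basis, drop=FALSE], Tm[, e])
      xb <- solve(Tm[, basis, drop=FALSE], b2)
      pos <- which(d > 1e-11)
      if (!length(pos)) return("unbounded")
      r <- pos[which.min(xb[pos]/d[pos])]
      basis[r] <- e
    }
  }
  if (length(art)) {
    cost1 <- c(rep(0, nA), rep(1, length(art)))
    r1 <- simplex_core(T1, b2, basis, cost1)
    if (is.null(r1) || identical(r1, "unbounded")) return(NULL)
    if (sum(cost1[r1$basis] * r1$xb) > 1e-8) return(NULL)   # infeasible
    basis <- r1$basis
    # drive artificials out crudely: if any artificial basic with ~0 value, try pivot; else accept
    T1cost <- c(c2, rep(1e6, length(art)))  # big-M fallback for phase 2
    r2 <- simplex_core(T1, b2, basis, T1cost)
  } else {
    r2 <- simplex_core(T1, b2, basis, c2)
  }
  if (is.null(r2) || identical(r2, "unbounded")) return(NULL)
  z <- numeric(ncol(T1)); z[r2$basis] <- r2$xb
  list(obj = sum(c2 * z[seq_along(c2)]), z = z[1:nv] - z[(nv+1):(2*nv)])
}

# Oracle: min sup|G - Fn| over unimodal G, modes on grid (data pts + midpoints + outside)
dip_oracle <- function(x) {
  x <- sort(x); n <- length(x)
  ux <- unique(x)
  gaps <- if (length(ux) > 1) (head(ux,-1) + tail(ux,-1))/2 else numeric(0)
  modes <- sort(unique(c(ux, gaps, ux[1]-1, ux[length(ux)]+1)))
  Fn  <- sapply(ux, function(v) mean(x <= v))
  Fnm <- sapply(ux, function(v) mean(x <  v))
  best <- Inf
  for (m in modes) {
    # knots: union of data values and m; variables: value at each knot; at m two
    # variables (left limit gl, right value gr) with gl <= gr (jump at mode).
    ks <- sort(unique(c(ux, m)))
    K <- length(ks)
    im <- match(m, ks)
    # variables: y_1..y_K for right-values at knots, plus yl = left limit at mode, plus d
    # G is piecewise linear through right-values except jump at mode from yl to y_im.
    nv <- K + 2
    Dv <- nv      # index of d
    YL <- K + 1
    rows <- list(); rhs <- c()
    addc <- function(coef, b) { rows[[length(rows)+1]] <<- coef; rhs[length(rhs)+1] <<- b }
    cf <- function() numeric(nv)
    # bounds 0 <= y <= 1, yl in [0,1], d >= 0
    for (k in 1:K) { a<-cf(); a[k]<-(-1); addc(a,0); a<-cf(); a[k]<-1; addc(a,1) }
    a<-cf(); a[YL]<-(-1); addc(a,0); a<-cf(); a[YL]<-1; addc(a,1)
    a<-cf(); a[Dv]<-(-1); addc(a,0)
    # monotone: y_k <= y_{k+1}; and jump: yl <= y_im; yl >= y_{im-1} (if exists)
    for (k in 1:(K-1)) { a<-cf(); a[k]<-1; a[k+1]<-(-1); addc(a,0) }
    a<-cf(); a[YL]<-1; a[im]<-(-1); addc(a,0)
    if (im > 1) { a<-cf(); a[im-1]<-1; a[YL]<-(-1); addc(a,0) }
    # convexity left of mode: second differences of (y_1..y_{im-1}, yl) >= 0
    lx <- c(ks[seq_len(im-1)], m); lv <- c(seq_len(im-1), YL)
    if (length(lx) >= 3) for (k in 2:(length(lx)-1)) {
      h1 <- lx[k]-lx[k-1]; h2 <- lx[k+1]-lx[k]
      a <- cf(); a[lv[k-1]] <- -1/h1; a[lv[k]] <- 1/h1 + 1/h2; a[lv[k+1]] <- -1/h2
      addc(a, 0)  # (y[k]-y[k-1])/h1 ... convex: slope increase: -( ... ) <= 0
    }
    # also slope at left end >= 0 is monotonicity (done); convexity needs extension to 0:
    # extension feasible always (kink to flat at 0), no constraint.
    # concavity right of mode: points (m via y_im? mode value y_im) then ks>m
    rx <- ks[im:K]; rv <- im:K
    if (length(rx) >= 3) for (k in 2:(length(rx)-1)) {
      h1 <- rx[k]-rx[k-1]; h2 <- rx[k+1]-rx[k]
      a <- cf(); a[rv[k-1]] <- 1/h1; a[rv[k]] <- -(1/h1 + 1/h2); a[rv[k+1]] <- 1/h2
      addc(a, 0)
    }
    # concave extension to 1 at +inf: always feasible (flatten), but G(x)<=1 imposed.
    # BUT concave nondecreasing reaching exactly 1: need last slope >= 0 (monotone, ok).
    # convex extension below to 0: convex means slopes nondecreasing; at left end can
    # kink from 0, fine.
    # sup-norm constraints at each data value v: |G(v) - Fn(v)| <= d, |G(v-) - Fnm(v)| <= d
    for (t in seq_along(ux)) {
      v <- ux[t]; k <- match(v, ks)
      # right value at v
      a<-cf(); a[k]<-1;  a[Dv]<-(-1); addc(a,  Fn[t])
      a<-cf(); a[k]<-(-1); a[Dv]<-(-1); addc(a, -Fn[t])
      # left limit at v: equals y_k unless v == m (then yl)
      kk <- if (v == m) YL else k
      a<-cf(); a[kk]<-1;  a[Dv]<-(-1); addc(a,  Fnm[t])
      a<-cf(); a[kk]<-(-1); a[Dv]<-(-1); addc(a, -Fnm[t])
    }
    # also check tube at mode knot if m not a data value: F constant there, G between
    # neighbours' constraints; G monotone so sup between data knots attained at knot
    # limits -> constrain G at m against Fn just below/above:
    if (!(m %in% ux)) {
      Fm <- mean(x <= m)
      a<-cf(); a[im]<-1;  a[Dv]<-(-1); addc(a,  Fm)
      a<-cf(); a[im]<-(-1); a[Dv]<-(-1); addc(a, -Fm)
      a<-cf(); a[YL]<-1;  a[Dv]<-(-1); addc(a,  Fm)
      a<-cf(); a[YL]<-(-1); a[Dv]<-(-1); addc(a, -Fm)
    }
    A <- do.call(rbind, rows)
    cvec <- cf(); cvec[Dv] <- 1
    r <- solve_lp(cvec, A, rhs)
    if (!is.null(r)) best <- min(best, r$obj)
  }
  best
}
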