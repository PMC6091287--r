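## Powell's direction-set minimizer.
##
## Classic derivative-free scheme: cycle through a set of search directions
## (initially the coordinate axes), performing a Brent line search along
## each; after a full cycle, optionally replace the direction of largest
## decrease with the net displacement direction (Powell's update rule, in
## its standard safeguarded form) so the set adapts to the valley geometry.
## Convergence is declared when the parameter vector moves less than `xtol`
## in one full cycle. No gradients are used.

powellOptim <- function(fn, par, xtol = 1e-4, maxIter = 100L,
                        bracket = 10, lineTol = NULL) {
  n <- length(par)
  if (is.null(lineTol)) lineTol <- max(xtol / 2, 1e-4)
  dirs <- diag(n)
  p <- par
  fval <- fn(p)
  trace <- fval
  iter <- 0L
  repeat {
    iter <- iter + 1L
    p0 <- p; f0 <- fval
    del <- 0; ibig <- 0L
    for (i in seq_len(n)) {
      fprev <- fval
      ls <- powellLineSearch(fn, p, dirs[, i], fval, bracket, lineTol)
      p <- ls$p; fval <- ls$f
      trace <- c(trace, fval)
      if (fprev - fval > del) { del <- fprev - fval; ibig <- i }
    }
    if (max(abs(p - p0)) < xtol || iter >= maxIter) break
    ## direction replacement: try the extrapolated point 2p - p0 and apply
    ## the standard acceptance test before searching along p - p0
    pe <- 2 * p - p0
    fe <- fn(pe)
    if (fe < f0 && ibig > 0L) {
      tcrit <- 2 * (f0 - 2 * fval + fe) * (f0 - fval - del)^2 -
        del * (f0 - fe)^2
      if (tcrit < 0) {
        d <- p - p0
        nd <- sqrt(sum(d * d))
        if (nd > xtol) {
          d <- d / nd
          ls <- powellLineSearch(fn, p, d, fval, bracket, lineTol)
          p <- ls$p; fval <- ls$f
          trace <- c(trace, fval)
          dirs[, ibig] <- dirs[, n]
          dirs[, n] <- d
        }
      }
    }
  }
  list(par = p, value = fval, iterations = iter, trace = trace)
}

## Brent (golden-section / parabolic) search along direction d from p,
## bounded to |step| <= bracket with one outward expansion if the optimum
## sits at the edge. A point worse than the start is never accepted.
powellLineSearch <- function(fn, p, d, f0, bracket, lineTol) {
  g <- function(a) fn(p + a * d)
  opt <- stats::optimize(g, interval = c(-bracket, bracket), tol = lineTol)
  if (abs(opt$minimum) > 0.9 * bracket) {
    s <- sign(opt$minimum)
    opt2 <- stats::optimize(g, interval = sort(c(s * 0.5 * bracket,
                                                 s * 4 * bracket)),
                            tol = lineTol)
    if (opt2$objective < opt$objective) opt <- opt2
  }
  if (opt$objective < f0) list(p = p + opt$minimum * d, f = opt$objective)
  else list(p = p, f = f0)
}
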