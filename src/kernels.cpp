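#include <Rcpp.h>
using namespace Rcpp;

// Column-wise cumulative sum. Workhorse for state variables (chilling,
// forcing) that accumulate day by day within each enclosure-year column.
// [[Rcpp::export]]
NumericMatrix col_cumsum(NumericMatrix x) {
  int nr = x.nrow(), nc = x.ncol();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    double s = 0.0;
    for (int i = 0; i < nr; ++i) {
      s += x(i, j);
      out(i, j) = s;
    }
  }
  return out;
}

// For each column j: accumulate rates from row start[j] (1-based) and return
// the first row index (1-based) at which the running sum reaches thresh[j].
// Returns 0 when the threshold is never reached (no-transition sentinel) or
// when start[j] is 0 (upstream sentinel, e.g. chilling never released).
// Rates before the start row do not count.
// [[Rcpp::export]]
IntegerVector first_crossing(NumericMatrix rates, IntegerVector start,
                             NumericVector thresh) {
  int nr = rates.nrow(), nc = rates.ncol();
  if (start.size() != nc || thresh.size() != nc)
    stop("start/thresh length must equal ncol(rates)");
  IntegerVector out(nc);
  for (int j = 0; j < nc; ++j) {
    int s0 = start[j];
    if (s0 < 1) { out[j] = 0; continue; }
    double s = 0.0;
    int hit = 0;
    for (int i = s0 - 1; i < nr; ++i) {
      s += rates(i, j);
      if (s >= thresh[j]) { hit = i + 1; break; }
    }
    out[j] = hit;
  }
  return out;
}

// First row (1-based, at or after start[j]) where state(i,j) >= thresh(i,j),
// for precomputed state/threshold matrices (used when the requirement itself
// varies through time, e.g. alternating and unified models). 0 if never.
// [[Rcpp::export]]
IntegerVector first_ge(NumericMatrix state, NumericMatrix thresh,
                       IntegerVector start) {
  int nr = state.nrow(), nc = state.ncol();
  if (thresh.nrow() != nr || thresh.ncol() != nc)
    stop("state and thresh must have identical dimensions");
  IntegerVector out(nc);
  for (int j = 0; j < nc; ++j) {
    int s0 = start[j];
    if (s0 < 1) { out[j] = 0; continue; }
    int hit = 0;
    for (int i = s0 - 1; i < nr; ++i) {
      if (state(i, j) >= thresh(i, j)) { hit = i + 1; break; }
    }
    out[j] = hit;
  }
  return out;
}
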