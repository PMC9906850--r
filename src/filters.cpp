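#include <Rcpp.h>
using namespace Rcpp;

// Forward-sweep speed filter. Keeps the first fix of each group; a later fix is
// dropped when the straight-line speed from the last *retained* fix exceeds
// speed_max. Groups (tags) are contiguous blocks of equal integers.
// [[Rcpp::export]]
LogicalVector speed_filter_cpp(NumericVector x, NumericVector y,
                               NumericVector t_s, IntegerVector group,
                               double speed_max) {
  int n = x.size();
  LogicalVector keep(n);
  if (n == 0) return keep;
  int last = -1;         // index of last retained fix in current group
  int cur_group = group[0];
  for (int i = 0; i < n; ++i) {
    if (group[i] != cur_group) { cur_group = group[i]; last = -1; }
    if (last < 0) { keep[i] = true; last = i; continue; }
    double dt = t_s[i] - t_s[last];
    double dx = x[i] - x[last];
    double dy = y[i] - y[last];
    double dist = std::sqrt(dx * dx + dy * dy);
    // dt <= 0 cannot happen after dedup/sort; treat defensively as over-speed
    if (dt <= 0.0 || dist / dt > speed_max) {
      keep[i] = false;
    } else {
      keep[i] = true; last = i;
    }
  }
  return keep;
}

// Running-centroid stop detection within one night. A candidate run grows while
// each incoming fix lies within `radius` of the run's running centroid; a closed
// run becomes a stop when it lasted at least `min_dur` seconds. Returns 1-based
// stop-run ids, 0 for move fixes. A single fix night is one (zero-length) stop.
// [[Rcpp::export]]
IntegerVector stop_label_cpp(NumericVector x, NumericVector y,
                             NumericVector t_s, double radius, double min_dur) {
  int n = x.size();
  IntegerVector lab(n, 0);
  if (n == 0) return lab;
  if (n == 1) { lab[0] = 1; return lab; }
  int run_start = 0, next_id = 1;
  double cx = x[0], cy = y[0];
  int run_n = 1;
  for (int i = 1; i <= n; ++i) {
    bool close_run = true;
    if (i < n) {
      double dx = x[i] - cx, dy = y[i] - cy;
      if (std::sqrt(dx * dx + dy * dy) <= radius) {
        run_n++;
        cx += (x[i] - cx) / run_n;
        cy += (y[i] - cy) / run_n;
        close_run = false;
      }
    }
    if (close_run) {
      double dur = t_s[i - 1] - t_s[run_start];
      if (dur >= min_dur) {
        for (int j = run_start; j < i; ++j) lab[j] = next_id;
        next_id++;
      }
      if (i < n) { run_start = i; cx = x[i]; cy = y[i]; run_n = 1; }
    }
  }
  return lab;
}

// Greedy temporal thinning: keep a fix when at least `interval` seconds have
// elapsed since the last kept fix. Groups restart the clock.
// [[Rcpp::export]]
LogicalVector thin_times_cpp(NumericVector t_s, IntegerVector group,
                             double interval) {
  int n = t_s.size();
  LogicalVector keep(n);
  if (n == 0) return keep;
  double last = R_NegInf;
  int cur_group = group[0];
  bool first = true;
  for (int i = 0; i < n; ++i) {
    if (group[i] != cur_group) { cur_group = group[i]; first = true; }
    if (first || t_s[i] - last >= interval) {
      keep[i] = true; last = t_s[i]; first = false;
    }
  }
  return keep;
}
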