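#include <Rcpp.h>
using namespace Rcpp;

// Clinic-day recursion over a batch of show vectors.
//
// Patients are pre-sorted into service order (slot index, then within-slot
// priority). `a` holds each patient's slot start in minutes from session
// start, `dur` is the deterministic service time (= slot duration),
// `sess_len` the session length. `S` is an m x n 0/1 matrix of show
// vectors, one row per realization. Waits are zero for no-shows; idle and
// overtime follow the conservation identities
//   idle = max(sess_len, last_completion) - dur * n_shown
//   overtime = max(0, last_completion - sess_len).

// [[Rcpp::export]]
List cpp_day_eval(NumericVector a, double dur, double sess_len,
                  IntegerMatrix S) {
  const int m = S.nrow(), n = S.ncol();
  NumericMatrix W(m, n);
  NumericVector idle(m), overtime(m);
  for (int r = 0; r < m; ++r) {
    double free_at = 0.0;
    int shown = 0;
    for (int j = 0; j < n; ++j) {
      if (S(r, j) == 1) {
        double start = std::max(a[j], free_at);
        W(r, j) = start - a[j];
        free_at = start + dur;
        ++shown;
      }
    }
    double horizon = std::max(sess_len, free_at);
    idle[r] = horizon - dur * shown;
    overtime[r] = std::max(0.0, free_at - sess_len);
  }
  return List::create(_["wait"] = W, _["idle"] = idle,
                      _["overtime"] = overtime);
}

// Probability-weighted expectations of the same recursion, without
// materializing the wait matrix. `w` are realization weights summing to 1
// (exact enumeration) or 1/m each (Monte Carlo). `ord` maps service
// position j to the 0-based column of `S` holding that patient's
// indicator, so callers can keep one roster-ordered show matrix across
// many candidate assignments; `a` is indexed by service position. The
// returned waits are in service order.

// [[Rcpp::export]]
List cpp_expected_eval(NumericVector a, double dur, double sess_len,
                       IntegerMatrix S, NumericVector w, IntegerVector ord) {
  const int m = S.nrow(), n = S.ncol();
  NumericVector ewait(n);
  double eidle = 0.0, eot = 0.0;
  for (int r = 0; r < m; ++r) {
    const double wr = w[r];
    if (wr == 0.0) continue;
    double free_at = 0.0;
    int shown = 0;
    for (int j = 0; j < n; ++j) {
      if (S(r, ord[j]) == 1) {
        double start = std::max(a[j], free_at);
        ewait[j] += wr * (start - a[j]);
        free_at = start + dur;
        ++shown;
      }
    }
    eidle += wr * (std::max(sess_len, free_at) - dur * shown);
    eot += wr * std::max(0.0, free_at - sess_len);
  }
  return List::create(_["wait"] = ewait, _["idle"] = eidle,
                      _["overtime"] = eot);
}

// ---- objective evaluation and local search ---------------------------------
//
// Objective variants: 0 = TRADITIONAL (weighted total expected wait),
// 1 = RACE_AWARE (n * worst group mean show-conditional expected wait),
// 2 = RACE_UNAWARE (n * worst individual show-conditional expected wait).
// The fair variants use waits conditional on attendance, E[wait]/p, so
// that a patient's own no-show rate does not mask the waiting they face
// when they do come. Idle and overtime terms are common to all variants.
// `slots` is 1-based and roster-aligned; within-slot priority is canonical
// roster order, realized here by a stable counting sort of patients by
// slot.

namespace {

void service_order_of(const IntegerVector &slots, int m, std::vector<int> &ord) {
  const int n = slots.size();
  std::vector<int> count(m + 2, 0);
  for (int i = 0; i < n; ++i) ++count[slots[i] + 1];
  for (int s = 1; s <= m + 1; ++s) count[s] += count[s - 1];
  ord.resize(n);
  for (int i = 0; i < n; ++i) ord[count[slots[i]]++] = i;
}

// `sec` receives the TRADITIONAL-cost value, used by the local search as a
// lexicographic tie-breaker so min-max objectives do not strand the search
// on plateaus where only the maximum matters.
double objective_of(const IntegerMatrix &S, const NumericVector &w,
                    double dur, double sess_len, const IntegerVector &slots,
                    int m, int variant, double w_wait, double w_idle,
                    double w_ot, const IntegerVector &group_idx,
                    int n_groups, const NumericVector &p,
                    std::vector<double> &ewait, std::vector<int> &ord,
                    double *sec = nullptr) {
  const int n = slots.size();
  const int nrow = S.nrow();
  service_order_of(slots, m, ord);
  std::fill(ewait.begin(), ewait.end(), 0.0);
  double eidle = 0.0, eot = 0.0;
  for (int r = 0; r < nrow; ++r) {
    const double wr = w[r];
    if (wr == 0.0) continue;
    double free_at = 0.0;
    int shown = 0;
    for (int j = 0; j < n; ++j) {
      const int i = ord[j];
      if (S(r, i) == 1) {
        const double a = (slots[i] - 1) * dur;
        const double start = std::max(a, free_at);
        ewait[i] += wr * (start - a);
        free_at = start + dur;
        ++shown;
      }
    }
    eidle += wr * (std::max(sess_len, free_at) - dur * shown);
    eot += wr * std::max(0.0, free_at - sess_len);
  }
  double total_wait = 0.0;
  for (int i = 0; i < n; ++i) total_wait += ewait[i];
  if (sec) *sec = w_wait * total_wait + w_idle * eidle + w_ot * eot;
  double wait_term = 0.0;
  if (variant == 0) {
    wait_term = total_wait;
  } else if (variant == 2) {
    double mx = 0.0;
    for (int i = 0; i < n; ++i) {
      const double cw = p[i] > 0.0 ? ewait[i] / p[i] : 0.0;
      mx = std::max(mx, cw);
    }
    wait_term = n * mx;
  } else {
    std::vector<double> gsum(n_groups, 0.0);
    std::vector<int> gcnt(n_groups, 0);
    for (int i = 0; i < n; ++i) {
      gsum[group_idx[i]] += p[i] > 0.0 ? ewait[i] / p[i] : 0.0;
      ++gcnt[group_idx[i]];
    }
    double mx = 0.0;
    for (int g = 0; g < n_groups; ++g) {
      if (gcnt[g] > 0) mx = std::max(mx, gsum[g] / gcnt[g]);
    }
    wait_term = n * mx;
  }
  return w_wait * wait_term + w_idle * eidle + w_ot * eot;
}

} // namespace

// [[Rcpp::export]]
double cpp_objective(IntegerMatrix S, NumericVector w, double dur,
                     double sess_len, IntegerVector slots, int m,
                     int variant, NumericVector wts,
                     IntegerVector group_idx, int n_groups,
                     NumericVector p) {
  std::vector<double> ewait(slots.size());
  std::vector<int> ord;
  return objective_of(S, w, dur, sess_len, slots, m, variant, wts[0], wts[1],
                      wts[2], group_idx, n_groups, p, ewait, ord);
}

// First-improvement local search over single-patient moves and pairwise
// swaps, repeated until a full pass yields no improvement or `max_passes`
// passes have run. Moves that leave the objective unchanged but lower the
// TRADITIONAL cost are accepted, so min-max plateaus are traversed.
// Returns the improved slot vector and its objective.

// [[Rcpp::export]]
List cpp_local_search(IntegerMatrix S, NumericVector w, double dur,
                      double sess_len, IntegerVector slots0, int m,
                      int capacity, int variant, NumericVector wts,
                      IntegerVector group_idx, int n_groups,
                      NumericVector p, int max_passes) {
  const int n = slots0.size();
  IntegerVector slots = clone(slots0);
  std::vector<double> ewait(n);
  std::vector<int> ord;
  std::vector<int> load(m + 1, 0);
  for (int i = 0; i < n; ++i) ++load[slots[i]];
  double sec = 0.0, csec = 0.0;
  double obj = objective_of(S, w, dur, sess_len, slots, m, variant, wts[0],
                            wts[1], wts[2], group_idx, n_groups, p, ewait,
                            ord, &sec);
  auto better = [&](double cobj, double cs) {
    return cobj < obj - 1e-9 || (cobj < obj + 1e-9 && cs < sec - 1e-9);
  };
  for (int pass = 0; pass < max_passes; ++pass) {
    bool improved = false;
    for (int i = 0; i < n; ++i) {
      for (int s = 1; s <= m; ++s) {
        if (s == slots[i] || load[s] >= capacity) continue;
        const int old = slots[i];
        slots[i] = s;
        const double cobj = objective_of(S, w, dur, sess_len, slots, m,
                                         variant, wts[0], wts[1], wts[2],
                                         group_idx, n_groups, p, ewait, ord,
                                         &csec);
        if (better(cobj, csec)) {
          obj = std::min(obj, cobj);
          sec = csec;
          --load[old];
          ++load[s];
          improved = true;
        } else {
          slots[i] = old;
        }
      }
    }
    for (int i = 0; i < n - 1; ++i) {
      for (int j = i + 1; j < n; ++j) {
        if (slots[i] == slots[j]) continue;
        std::swap(slots[i], slots[j]);
        const double cobj = objective_of(S, w, dur, sess_len, slots, m,
                                         variant, wts[0], wts[1], wts[2],
                                         group_idx, n_groups, p, ewait, ord,
                                         &csec);
        if (better(cobj, csec)) {
          obj = std::min(obj, cobj);
          sec = csec;
          improved = true;
        } else {
          std::swap(slots[i], slots[j]);
        }
      }
    }
    // slot-content swaps: exchange the full occupancy of two slots, which
    // relocates overbooked blocks in one step
    for (int s1 = 1; s1 < m; ++s1) {
      for (int s2 = s1 + 1; s2 <= m; ++s2) {
        if (load[s1] == 0 && load[s2] == 0) continue;
        for (int i = 0; i < n; ++i) {
          if (slots[i] == s1) slots[i] = s2;
          else if (slots[i] == s2) slots[i] = s1;
        }
        const double cobj = objective_of(S, w, dur, sess_len, slots, m,
                                         variant, wts[0], wts[1], wts[2],
                                         group_idx, n_groups, p, ewait, ord,
                                         &csec);
        if (better(cobj, csec)) {
          obj = std::min(obj, cobj);
          sec = csec;
          std::swap(load[s1], load[s2]);
          improved = true;
        } else {
          for (int i = 0; i < n; ++i) {
            if (slots[i] == s1) slots[i] = s2;
            else if (slots[i] == s2) slots[i] = s1;
          }
        }
      }
    }
    if (!improved) break;
  }
  return List::create(_["slots"] = slots, _["obj"] = obj);
}
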