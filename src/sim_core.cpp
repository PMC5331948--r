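#include <Rcpp.h>
using namespace Rcpp;

// Event types written to the log.
enum EventType { EV_TRANSPOSITION = 1, EV_HTT = 2, EV_LOSS = 3, EV_HTT_BLOCKED = 4 };

namespace {

struct EventLog {
  std::vector<int> iter, type, fam, src, tgt, cnt;
  bool enabled;
  explicit EventLog(bool on) : enabled(on) {}
  void add(int it, int ty, int f, int s, int t, int c) {
    if (!enabled) return;
    iter.push_back(it);
    type.push_back(ty);
    fam.push_back(f);
    src.push_back(s);
    tgt.push_back(t);
    cnt.push_back(c);
  }
  IntegerMatrix matrix() const {
    int n = iter.size();
    IntegerMatrix m(n, 6);
    for (int i = 0; i < n; ++i) {
      m(i, 0) = iter[i];
      m(i, 1) = type[i];
      m(i, 2) = fam[i];
      m(i, 3) = src[i];
      m(i, 4) = tgt[i];
      m(i, 5) = cnt[i];
    }
    colnames(m) = CharacterVector::create("iteration", "type", "family",
                                          "source", "target", "count");
    return m;
  }
};

// Uniformly draw `take` of the proposed per-family gains (multivariate
// hypergeometric, sequential marginals). Modifies `gain` in place.
void thin_gains(std::vector<int>& gain, int total, int take) {
  int pool = total, left = take;
  for (size_t f = 0; f < gain.size() && left < pool; ++f) {
    if (gain[f] == 0) continue;
    int a = (int)R::rhyper(gain[f], pool - gain[f], left);
    pool -= gain[f];
    left -= a;
    gain[f] = a;
  }
}

} // namespace

// Core synchronous-iteration simulator of TE copy-number dynamics on a
// species network. Per iteration: (1) every copy duplicates in its genome
// with probability u, blocked when the genome is at capacity; (2) every copy
// attempts a horizontal transfer with probability u/rho towards a neighbour
// drawn proportionally to edge weight; establishment in a full genome either
// replaces a uniformly chosen resident copy (at_capacity_replace) or is
// rejected; (3) every copy is lost with probability loss_prob.
// Runs until htt_count >= target_htt, max_iter iterations, extinction, or
// (when stop_full is set) until every species carries the (single) family.
// [[Rcpp::export(name = ".sim_core")]]
List sim_core(IntegerMatrix copies_init,
              List nbr_idx,          // per-species 1-based neighbour ids
              List nbr_wt,           // per-species positive edge weights
              IntegerVector capacity,
              double u, double rho, double loss_prob,
              int target_htt, int max_iter,
              bool per_family_capacity,
              bool at_capacity_replace,
              bool log_events,
              bool track_spread,
              bool stop_full,
              int iter0, int htt0) {
  const int S = copies_init.nrow(), F = copies_init.ncol();
  IntegerMatrix copies = clone(copies_init);
  std::vector<long> tot(S, 0);
  for (int s = 0; s < S; ++s)
    for (int f = 0; f < F; ++f) tot[s] += copies(s, f);

  const double u_htt = u / rho;
  int htt_count = htt0;
  long n_blocked = 0, n_transpositions = 0;
  int iter = iter0;
  bool extinct = false;

  EventLog log(log_events);

  // first_pass[x-1] = first iteration at which x species carried >= 1 copy
  IntegerVector first_pass(track_spread ? S : 0, NA_INTEGER);
  int max_infected = 0;
  if (track_spread) {
    int inf = 0;
    for (int s = 0; s < S; ++s)
      if (tot[s] > 0) ++inf;
    for (int x = 1; x <= inf; ++x) first_pass[x - 1] = iter0;
    max_infected = inf;
  }

  std::vector<int> gain(F);

  while (iter - iter0 < max_iter && htt_count < target_htt) {
    if (stop_full && track_spread && max_infected >= S) break;
    ++iter;

    // (1) intragenomic transposition
    for (int s = 0; s < S; ++s) {
      if (tot[s] == 0) continue;
      if (per_family_capacity) {
        for (int f = 0; f < F; ++f) {
          int c = copies(s, f);
          if (c == 0 || c >= capacity[s]) continue;
          int g = (int)R::rbinom(c, u);
          if (g > capacity[s] - c) g = capacity[s] - c;
          if (g > 0) {
            copies(s, f) += g;
            tot[s] += g;
            n_transpositions += g;
            log.add(iter, EV_TRANSPOSITION, f + 1, s + 1, NA_INTEGER, g);
          }
        }
      } else {
        long room = capacity[s] - tot[s];
        if (room <= 0) continue;
        int G = 0;
        for (int f = 0; f < F; ++f) {
          int c = copies(s, f);
          gain[f] = c > 0 ? (int)R::rbinom(c, u) : 0;
          G += gain[f];
        }
        if (G == 0) continue;
        if (G > room) thin_gains(gain, G, (int)room);
        for (int f = 0; f < F; ++f) {
          if (gain[f] == 0) continue;
          copies(s, f) += gain[f];
          tot[s] += gain[f];
          n_transpositions += gain[f];
          log.add(iter, EV_TRANSPOSITION, f + 1, s + 1, NA_INTEGER, gain[f]);
        }
      }
    }

    // (2) horizontal transfer attempts; the run ends at the target'th success
    for (int s = 0; s < S && htt_count < target_htt; ++s) {
      if (tot[s] == 0) continue;
      IntegerVector nb = nbr_idx[s];
      if (nb.size() == 0) continue;
      NumericVector wt = nbr_wt[s];
      double wsum = 0.0;
      for (int k = 0; k < wt.size(); ++k) wsum += wt[k];
      for (int f = 0; f < F && htt_count < target_htt; ++f) {
        int c = copies(s, f);
        if (c == 0) continue;
        int att = (int)R::rbinom(c, u_htt);
        for (int a = 0; a < att && htt_count < target_htt; ++a) {
          // draw recipient proportional to edge weight
          double x = unif_rand() * wsum;
          int k = 0;
          while (k < wt.size() - 1 && x > wt[k]) x -= wt[k++];
          int r = nb[k] - 1;
          bool full = per_family_capacity ? copies(r, f) >= capacity[r]
                                          : tot[r] >= capacity[r];
          if (!full) {
            copies(r, f) += 1;
            tot[r] += 1;
            ++htt_count;
            log.add(iter, EV_HTT, f + 1, s + 1, r + 1, 1);
          } else if (at_capacity_replace && !per_family_capacity) {
            // evict a uniformly chosen resident copy, then establish
            long q = (long)(unif_rand() * tot[r]);
            int vf = 0;
            long acc = 0;
            for (; vf < F; ++vf) {
              acc += copies(r, vf);
              if (q < acc) break;
            }
            copies(r, vf) -= 1;
            copies(r, f) += 1;
            ++htt_count;
            log.add(iter, EV_LOSS, vf + 1, r + 1, NA_INTEGER, 1);
            log.add(iter, EV_HTT, f + 1, s + 1, r + 1, 1);
          } else {
            ++n_blocked;
            log.add(iter, EV_HTT_BLOCKED, f + 1, s + 1, r + 1, 1);
          }
        }
      }
    }

    // (3) stochastic copy loss (skipped in the instant the run ends)
    if (loss_prob > 0 && htt_count < target_htt) {
      for (int s = 0; s < S; ++s) {
        if (tot[s] == 0) continue;
        for (int f = 0; f < F; ++f) {
          int c = copies(s, f);
          if (c == 0) continue;
          int l = (int)R::rbinom(c, loss_prob);
          if (l > 0) {
            copies(s, f) -= l;
            tot[s] -= l;
            log.add(iter, EV_LOSS, f + 1, s + 1, NA_INTEGER, l);
          }
        }
      }
    }

    long grand = 0;
    int inf = 0;
    for (int s = 0; s < S; ++s) {
      grand += tot[s];
      if (tot[s] > 0) ++inf;
    }
    if (track_spread && inf > max_infected) {
      for (int x = max_infected + 1; x <= inf; ++x) first_pass[x - 1] = iter;
      max_infected = inf;
    }
    if (grand == 0) {
      extinct = true;
      break;
    }
  }

  bool truncated = (htt_count < target_htt) && !extinct &&
                   !(stop_full && track_spread && max_infected >= S);

  List out = List::create(
      _["copies"] = copies,
      _["iteration"] = iter,
      _["htt_count"] = htt_count,
      _["n_transpositions"] = (double)n_transpositions,
      _["n_capacity_rejected"] = (double)n_blocked,
      _["truncated"] = truncated,
      _["extinct"] = extinct,
      _["event_log"] = log.matrix());
  if (track_spread) out["first_passage"] = first_pass;
  return out;
}
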