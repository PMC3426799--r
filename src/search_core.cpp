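// Search engine: memoized family scoring and greedy hill-climbing with a
// visited cache, shared by all restarts of one search run. The R level
// owns the protocol (restart scheduling, candidate selection, RNG); this
// file owns the inner loop.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
using namespace Rcpp;

enum Metric { K2 = 0, DPSM = 1, BDE = 2, BIC = 3, MDL = 4 };

struct SearchCtx {
  std::vector<int> x;       // column-major, 0-based states
  int nrow, ncol;
  std::vector<int> arities;
  std::vector<double> w;
  double wtot;
  int metric;
  double lambda, ess;
  std::unordered_map<std::string, double> fcache;
  std::unordered_map<std::string, double> visited;
  std::vector<std::vector<std::vector<int> > > vstruct;
  std::vector<double> vscore;
};

static std::string family_key(int child, const std::vector<int>& par) {
  std::string k;
  k.reserve(par.size() + 1);
  k.push_back((char)(child + 1));
  for (size_t a = 0; a < par.size(); ++a) k.push_back((char)(par[a] + 1));
  return k;
}

static std::string struct_key_cpp(const std::vector<std::vector<int> >& parents) {
  std::string k;
  for (size_t i = 0; i < parents.size(); ++i) {
    for (size_t a = 0; a < parents[i].size(); ++a)
      k.push_back((char)(parents[i][a] + 1));
    k.push_back('\0');
  }
  return k;
}

// Family log-score on weighted counts; mirrors the R reference
// implementation (family_log_score) exactly.
static double family_score(SearchCtx& ctx, int child,
                           const std::vector<int>& parents) {
  std::string key = family_key(child, parents);
  std::unordered_map<std::string, double>::iterator it = ctx.fcache.find(key);
  if (it != ctx.fcache.end()) return it->second;

  int r = ctx.arities[child];
  int np = (int)parents.size();
  long q = 1;
  std::vector<long> radix(np);
  for (int a = 0; a < np; ++a) {
    radix[a] = q;
    q *= ctx.arities[parents[a]];
  }
  std::vector<double> cnt((size_t)q * r, 0.0);
  const int N = ctx.nrow;
  for (int row = 0; row < N; ++row) {
    long j = 0;
    for (int a = 0; a < np; ++a)
      j += (long)ctx.x[(size_t)parents[a] * N + row] * radix[a];
    cnt[(size_t)j * r + ctx.x[(size_t)child * N + row]] += ctx.w[row];
  }

  double val = 0.0;
  if (ctx.metric == K2 || ctx.metric == DPSM || ctx.metric == BDE) {
    double alpha = 1.0;
    if (ctx.metric == DPSM) alpha = ctx.lambda;
    else if (ctx.metric == BDE) alpha = ctx.ess / ((double)r * q);
    double lg_alpha = R::lgammafn(alpha);
    double lg_ralpha = R::lgammafn(r * alpha);
    val = q * lg_ralpha - (double)q * r * lg_alpha;
    for (long j = 0; j < q; ++j) {
      double nij = 0.0;
      for (int k = 0; k < r; ++k) {
        double c = cnt[(size_t)j * r + k];
        nij += c;
        val += R::lgammafn(alpha + c);
      }
      val -= R::lgammafn(r * alpha + nij);
    }
  } else {
    double ll = 0.0;
    for (long j = 0; j < q; ++j) {
      double nij = 0.0;
      for (int k = 0; k < r; ++k) nij += cnt[(size_t)j * r + k];
      if (nij <= 0) continue;
      for (int k = 0; k < r; ++k) {
        double c = cnt[(size_t)j * r + k];
        if (c > 0) ll += c * std::log(c / nij);
      }
    }
    double d = (double)(r - 1) * q;
    if (ctx.metric == BIC) {
      val = ll - d / 2.0 * std::log(ctx.wtot);
    } else { // MDL
      double dl_graph = np * std::log2((double)ctx.ncol);
      double dl_theta = 0.5 * std::log2(ctx.wtot) * d;
      double dl_data = -ll / M_LN2;
      val = -(dl_graph + dl_theta + dl_data);
    }
  }
  ctx.fcache[key] = val;
  return val;
}

static void record_visited(SearchCtx& ctx, const std::string& key,
                           const std::vector<std::vector<int> >& parents,
                           double score) {
  ctx.visited[key] = score;
  ctx.vstruct.push_back(parents);
  ctx.vscore.push_back(score);
}

// [[Rcpp::export(name = ".cpp_ctx_new")]]
SEXP cpp_ctx_new(IntegerMatrix x, IntegerVector arities, NumericVector w,
                 int metric, double lambda, double ess) {
  SearchCtx* ctx = new SearchCtx();
  ctx->nrow = x.nrow();
  ctx->ncol = x.ncol();
  ctx->x.resize((size_t)ctx->nrow * ctx->ncol);
  for (int j = 0; j < ctx->ncol; ++j)
    for (int i = 0; i < ctx->nrow; ++i)
      ctx->x[(size_t)j * ctx->nrow + i] = x(i, j) - 1;
  ctx->arities.assign(arities.begin(), arities.end());
  ctx->w.assign(w.begin(), w.end());
  ctx->wtot = 0.0;
  for (int i = 0; i < ctx->nrow; ++i) ctx->wtot += ctx->w[i];
  ctx->metric = metric;
  ctx->lambda = lambda;
  ctx->ess = ess;
  XPtr<SearchCtx> ptr(ctx, true);
  return ptr;
}

// [[Rcpp::export(name = ".cpp_family_score")]]
double cpp_family_score(SEXP ctx_, int child, IntegerVector parents) {
  XPtr<SearchCtx> ctx(ctx_);
  std::vector<int> par(parents.size());
  for (int a = 0; a < parents.size(); ++a) par[a] = parents[a] - 1;
  std::sort(par.begin(), par.end());
  return family_score(*ctx, child - 1, par);
}

static std::vector<std::vector<int> > list_to_parents(List parents, int n) {
  std::vector<std::vector<int> > out(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector p = parents[i];
    out[i].resize(p.size());
    for (int a = 0; a < p.size(); ++a) out[i][a] = p[a] - 1;
    std::sort(out[i].begin(), out[i].end());
  }
  return out;
}

static List parents_to_list(const std::vector<std::vector<int> >& parents) {
  List out(parents.size());
  for (size_t i = 0; i < parents.size(); ++i) {
    IntegerVector p(parents[i].size());
    for (size_t a = 0; a < parents[i].size(); ++a) p[a] = parents[i][a] + 1;
    out[i] = p;
  }
  return out;
}

// reach[a][b]: b reachable from a.
static void compute_reach(const std::vector<std::vector<int> >& children,
                          int n, std::vector<char>& reach) {
  std::fill(reach.begin(), reach.end(), 0);
  std::vector<int> stack;
  for (int a = 0; a < n; ++a) {
    stack.assign(children[a].begin(), children[a].end());
    while (!stack.empty()) {
      int v = stack.back();
      stack.pop_back();
      if (reach[(size_t)a * n + v]) continue;
      reach[(size_t)a * n + v] = 1;
      for (size_t c = 0; c < children[v].size(); ++c)
        stack.push_back(children[v][c]);
    }
  }
}

// any path j ~> i avoiding the direct edge j -> i?
static bool path_avoiding_edge(const std::vector<std::vector<int> >& children,
                               int j, int i, int n) {
  std::vector<char> seen(n, 0);
  std::vector<int> stack;
  for (size_t c = 0; c < children[j].size(); ++c)
    if (children[j][c] != i) stack.push_back(children[j][c]);
  while (!stack.empty()) {
    int v = stack.back();
    stack.pop_back();
    if (v == i) return true;
    if (seen[v]) continue;
    seen[v] = 1;
    for (size_t c = 0; c < children[v].size(); ++c)
      stack.push_back(children[v][c]);
  }
  return false;
}

// Greedy ascent; mirrors the protocol described in bn_search(). Ties keep
// the incumbent; equal-score neighbors resolve to the first in
// enumeration order (child, then add < delete < reverse, then parent).
// [[Rcpp::export(name = ".cpp_hill_climb")]]
List cpp_hill_climb(SEXP ctx_, List start, List candidates, int k) {
  XPtr<SearchCtx> xptr(ctx_);
  SearchCtx& ctx = *xptr;
  int n = ctx.ncol;
  std::vector<std::vector<int> > parents = list_to_parents(start, n);
  std::vector<std::vector<int> > cand = list_to_parents(candidates, n);

  std::vector<double> fam(n);
  double cur = 0.0;
  for (int i = 0; i < n; ++i) {
    fam[i] = family_score(ctx, i, parents[i]);
    cur += fam[i];
  }
  {
    std::string key = struct_key_cpp(parents);
    if (ctx.visited.find(key) == ctx.visited.end())
      record_visited(ctx, key, parents, cur);
  }

  std::vector<char> reach((size_t)n * n);
  std::vector<std::vector<int> > children(n);

  for (;;) {
    for (int i = 0; i < n; ++i) children[i].clear();
    for (int i = 0; i < n; ++i)
      for (size_t a = 0; a < parents[i].size(); ++a)
        children[parents[i][a]].push_back(i);
    compute_reach(children, n, reach);

    double best_score = R_NegInf;
    int best_i = -1, best_j = -1;
    std::vector<int> best_np, best_jp;
    bool best_isrev = false;

    std::vector<std::vector<int> > trial = parents;

    for (int i = 0; i < n; ++i) {
      const std::vector<int>& pi = parents[i];
      // additions
      if ((int)pi.size() < k) {
        for (size_t a = 0; a < cand[i].size(); ++a) {
          int j = cand[i][a];
          if (j == i) continue;
          if (std::find(pi.begin(), pi.end(), j) != pi.end()) continue;
          if (reach[(size_t)i * n + j]) continue; // i ~> j: would cycle
          std::vector<int> np = pi;
          np.insert(std::upper_bound(np.begin(), np.end(), j), j);
          trial[i] = np;
          std::string key = struct_key_cpp(trial);
          trial[i] = pi;
          if (ctx.visited.find(key) != ctx.visited.end()) continue;
          double sc = cur - fam[i] + family_score(ctx, i, np);
          trial[i] = np;
          record_visited(ctx, key, trial, sc);
          trial[i] = pi;
          if (sc > best_score) {
            best_score = sc; best_i = i; best_j = -1;
            best_np = np; best_isrev = false;
          }
        }
      }
      // deletions
      for (size_t a = 0; a < pi.size(); ++a) {
        int j = pi[a];
        std::vector<int> np;
        np.reserve(pi.size() - 1);
        for (size_t b = 0; b < pi.size(); ++b)
          if (pi[b] != j) np.push_back(pi[b]);
        trial[i] = np;
        std::string key = struct_key_cpp(trial);
        trial[i] = pi;
        if (ctx.visited.find(key) != ctx.visited.end()) continue;
        double sc = cur - fam[i] + family_score(ctx, i, np);
        trial[i] = np;
        record_visited(ctx, key, trial, sc);
        trial[i] = pi;
        if (sc > best_score) {
          best_score = sc; best_i = i; best_j = -1;
          best_np = np; best_isrev = false;
        }
      }
      // reversals: j -> i becomes i -> j
      for (size_t a = 0; a < pi.size(); ++a) {
        int j = pi[a];
        if ((int)parents[j].size() >= k) continue;
        if (std::find(cand[j].begin(), cand[j].end(), i) == cand[j].end())
          continue;
        if (path_avoiding_edge(children, j, i, n)) continue;
        std::vector<int> np;
        np.reserve(pi.size() - 1);
        for (size_t b = 0; b < pi.size(); ++b)
          if (pi[b] != j) np.push_back(pi[b]);
        std::vector<int> jp = parents[j];
        jp.insert(std::upper_bound(jp.begin(), jp.end(), i), i);
        trial[i] = np;
        trial[j] = jp;
        std::string key = struct_key_cpp(trial);
        trial[i] = pi;
        trial[j] = parents[j];
        if (ctx.visited.find(key) != ctx.visited.end()) continue;
        double sc = cur - fam[i] + family_score(ctx, i, np)
                        - fam[j] + family_score(ctx, j, jp);
        trial[i] = np;
        trial[j] = jp;
        record_visited(ctx, key, trial, sc);
        trial[i] = pi;
        trial[j] = parents[j];
        if (sc > best_score) {
          best_score = sc; best_i = i; best_j = j;
          best_np = np; best_jp = jp; best_isrev = true;
        }
      }
    }

    if (best_i < 0 || best_score <= cur) break;
    parents[best_i] = best_np;
    fam[best_i] = family_score(ctx, best_i, best_np);
    if (best_isrev) {
      parents[best_j] = best_jp;
      fam[best_j] = family_score(ctx, best_j, best_jp);
    }
    cur = best_score;
  }

  return List::create(Named("parents") = parents_to_list(parents),
                      Named("score") = cur);
}

// Candidate parent selection: rank prospective parents of each node by the
// family-score gain of adding them to the node's current parent set
// (current parents are always kept). Ties resolve by ascending node index.
// With no current structure this reduces to ranking single-edge scores.
// [[Rcpp::export(name = ".cpp_select_candidates")]]
List cpp_select_candidates(SEXP ctx_, List current, int k) {
  XPtr<SearchCtx> xptr(ctx_);
  SearchCtx& ctx = *xptr;
  int n = ctx.ncol;
  std::vector<std::vector<int> > cur = list_to_parents(current, n);
  List out(n);
  for (int i = 0; i < n; ++i) {
    std::vector<int> keep = cur[i];
    int room = k - (int)keep.size();
    if (room > 0) {
      double base = family_score(ctx, i, cur[i]);
      std::vector<std::pair<double, int> > gains;
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        if (std::find(cur[i].begin(), cur[i].end(), j) != cur[i].end())
          continue;
        std::vector<int> np = cur[i];
        np.insert(std::upper_bound(np.begin(), np.end(), j), j);
        gains.push_back(std::make_pair(family_score(ctx, i, np) - base, j));
      }
      std::stable_sort(gains.begin(), gains.end(),
                       [](const std::pair<double, int>& a,
                          const std::pair<double, int>& b) {
                         if (a.first != b.first) return a.first > b.first;
                         return a.second < b.second;
                       });
      int take = std::min(room, (int)gains.size());
      for (int t = 0; t < take; ++t) keep.push_back(gains[t].second);
      std::sort(keep.begin(), keep.end());
    }
    IntegerVector v((int)keep.size());
    for (size_t a = 0; a < keep.size(); ++a) v[a] = keep[a] + 1;
    out[i] = v;
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_visited_n")]]
int cpp_visited_n(SEXP ctx_) {
  XPtr<SearchCtx> ctx(ctx_);
  return (int)ctx->vscore.size();
}

// [[Rcpp::export(name = ".cpp_visited_get")]]
List cpp_visited_get(SEXP ctx_, int idx) {
  XPtr<SearchCtx> ctx(ctx_);
  return parents_to_list(ctx->vstruct[(size_t)idx - 1]);
}

// Top m distinct visited structures by score (ties in visit order).
// [[Rcpp::export(name = ".cpp_top_networks")]]
List cpp_top_networks(SEXP ctx_, int m) {
  XPtr<SearchCtx> ctx(ctx_);
  int nv = (int)ctx->vscore.size();
  int take = std::min(m, nv);
  std::vector<int> idx(nv);
  for (int i = 0; i < nv; ++i) idx[i] = i;
  std::partial_sort(idx.begin(), idx.begin() + take, idx.end(),
                    [&](int a, int b) {
                      if (ctx->vscore[a] != ctx->vscore[b])
                        return ctx->vscore[a] > ctx->vscore[b];
                      return a < b;
                    });
  List nets(take);
  NumericVector scores(take);
  for (int t = 0; t < take; ++t) {
    nets[t] = parents_to_list(ctx->vstruct[idx[t]]);
    scores[t] = ctx->vscore[idx[t]];
  }
  return List::create(Named("networks") = nets, Named("scores") = scores);
}
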