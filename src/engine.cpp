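#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <cmath>
#include <memory>
#include <queue>
#include <string>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// 8-puzzle permutation ranking (Lehmer code).  States are 9-character digit
// strings in row-major order, '0' marking the blank.  Ranks run 0..362879.
// ---------------------------------------------------------------------------

static const int FACT[10] = {1, 1, 2, 6, 24, 120, 720, 5040, 40320, 362880};

static inline int rank_tiles(const std::array<int, 9>& p) {
  int r = 0;
  for (int i = 0; i < 9; ++i) {
    int c = 0;
    for (int j = i + 1; j < 9; ++j)
      if (p[j] < p[i]) ++c;
    r += c * FACT[8 - i];
  }
  return r;
}

static inline void unrank_tiles(int r, std::array<int, 9>& p) {
  std::array<int, 9> avail = {0, 1, 2, 3, 4, 5, 6, 7, 8};
  int m = 9;
  for (int i = 0; i < 9; ++i) {
    int f = FACT[8 - i];
    int idx = r / f;
    r %= f;
    p[i] = avail[idx];
    for (int k = idx; k < m - 1; ++k) avail[k] = avail[k + 1];
    --m;
  }
}

static std::array<int, 9> tiles_from_string(const std::string& s) {
  if (s.size() != 9) stop("puzzle state must be a 9-character digit string");
  std::array<int, 9> p;
  std::array<int, 9> seen;
  seen.fill(0);
  for (int i = 0; i < 9; ++i) {
    char c = s[i];
    if (c < '0' || c > '8') stop("puzzle state may only contain digits 0-8");
    p[i] = c - '0';
    seen[p[i]]++;
  }
  for (int i = 0; i < 9; ++i)
    if (seen[i] != 1) stop("puzzle state must contain each of 0-8 exactly once");
  return p;
}

// Exhaustive breadth-first search from `goal` over the reachable half of the
// 9! state space.  Returns, for every permutation rank, the optimal move
// count to the goal, or -1 for unreachable (odd-parity) states.  This is the
// optimality oracle and the instance-difficulty labeller; it shares no code
// with the A* engine below.
// [[Rcpp::export]]
IntegerVector cpp_bfs_distances(std::string goal) {
  std::array<int, 9> g = tiles_from_string(goal);
  std::vector<int> dist(362880, -1);
  std::vector<int> cur, nxt;
  int r0 = rank_tiles(g);
  dist[r0] = 0;
  cur.push_back(r0);
  int d = 0;
  std::array<int, 9> p, q;
  static const int DR[4] = {-1, 1, 0, 0};
  static const int DC[4] = {0, 0, -1, 1};
  while (!cur.empty()) {
    nxt.clear();
    for (size_t ci = 0; ci < cur.size(); ++ci) {
      unrank_tiles(cur[ci], p);
      int b = 0;
      while (p[b] != 0) ++b;
      int br = b / 3, bc = b % 3;
      for (int k = 0; k < 4; ++k) {
        int nr = br + DR[k], nc = bc + DC[k];
        if (nr < 0 || nr > 2 || nc < 0 || nc > 2) continue;
        q = p;
        std::swap(q[b], q[nr * 3 + nc]);
        int rq = rank_tiles(q);
        if (dist[rq] < 0) {
          dist[rq] = d + 1;
          nxt.push_back(rq);
        }
      }
    }
    cur.swap(nxt);
    ++d;
  }
  return IntegerVector(dist.begin(), dist.end());
}

// [[Rcpp::export]]
int cpp_rank_state(std::string state) {
  std::array<int, 9> p = tiles_from_string(state);
  return rank_tiles(p);
}

// [[Rcpp::export]]
CharacterVector cpp_unrank_states(IntegerVector ranks) {
  CharacterVector out(ranks.size());
  std::array<int, 9> p;
  for (R_xlen_t i = 0; i < ranks.size(); ++i) {
    int r = ranks[i];
    if (r < 0 || r > 362879) stop("rank out of range");
    unrank_tiles(r, p);
    std::string s(9, '0');
    for (int k = 0; k < 9; ++k) s[k] = static_cast<char>('0' + p[k]);
    out[i] = s;
  }
  return out;
}

// Sum over non-blank tiles of Manhattan displacement to the tile's goal cell.
// [[Rcpp::export]]
double cpp_puzzle_manhattan(std::string state, std::string goal) {
  std::array<int, 9> s = tiles_from_string(state);
  std::array<int, 9> g = tiles_from_string(goal);
  std::array<int, 9> goal_pos;
  for (int i = 0; i < 9; ++i) goal_pos[g[i]] = i;
  double h = 0;
  for (int i = 0; i < 9; ++i) {
    if (s[i] == 0) continue;
    int gp = goal_pos[s[i]];
    h += std::abs(i / 3 - gp / 3) + std::abs(i % 3 - gp % 3);
  }
  return h;
}

// ---------------------------------------------------------------------------
// Search domains
// ---------------------------------------------------------------------------

struct Succ {
  std::string s;
  double cost;
};

class Domain {
 public:
  virtual ~Domain() {}
  virtual void successors(const std::string& s, std::vector<Succ>& out) = 0;
  virtual double heuristic(const std::string& s) = 0;
  virtual bool is_goal(const std::string& s) = 0;
};

class PuzzleDomain : public Domain {
  std::array<int, 9> goal_pos_;
  std::string goal_;

 public:
  explicit PuzzleDomain(const std::string& goal) : goal_(goal) {
    std::array<int, 9> g = tiles_from_string(goal);
    for (int i = 0; i < 9; ++i) goal_pos_[g[i]] = i;
  }
  void successors(const std::string& s, std::vector<Succ>& out) {
    out.clear();
    int b = 0;
    while (s[b] != '0') ++b;
    int br = b / 3, bc = b % 3;
    static const int DR[4] = {-1, 1, 0, 0};
    static const int DC[4] = {0, 0, -1, 1};
    for (int k = 0; k < 4; ++k) {
      int nr = br + DR[k], nc = bc + DC[k];
      if (nr < 0 || nr > 2 || nc < 0 || nc > 2) continue;
      std::string t = s;
      std::swap(t[b], t[nr * 3 + nc]);
      out.push_back({t, 1.0});
    }
  }
  double heuristic(const std::string& s) {
    double h = 0;
    for (int i = 0; i < 9; ++i) {
      int tile = s[i] - '0';
      if (tile == 0) continue;
      int gp = goal_pos_[tile];
      h += std::abs(i / 3 - gp / 3) + std::abs(i % 3 - gp % 3);
    }
    return h;
  }
  bool is_goal(const std::string& s) { return s == goal_; }
};

static inline void parse_cell(const std::string& s, int& r, int& c) {
  r = 0;
  c = 0;
  size_t i = 0;
  for (; i < s.size() && s[i] != ','; ++i) r = r * 10 + (s[i] - '0');
  for (++i; i < s.size(); ++i) c = c * 10 + (s[i] - '0');
}

static inline std::string cell_str(int r, int c) {
  return std::to_string(r) + "," + std::to_string(c);
}

// Occupancy grid, 0-based (row, col) cells serialised as "r,c".  4-connected
// unit moves by default; 8-connected adds sqrt(2) diagonals with corner
// cutting through blocked orthogonal neighbours forbidden.  The straight-line
// (Euclidean) heuristic is admissible and consistent for both move sets.
class GridDomain : public Domain {
  int W_, H_, conn_;
  std::vector<char> blocked_;
  int gr_, gc_;

 public:
  GridDomain(LogicalMatrix b, IntegerVector goal, int connectivity)
      : W_(b.ncol()), H_(b.nrow()), conn_(connectivity) {
    blocked_.resize(static_cast<size_t>(H_) * W_);
    for (int r = 0; r < H_; ++r)
      for (int c = 0; c < W_; ++c) blocked_[r * W_ + c] = b(r, c) ? 1 : 0;
    gr_ = goal[0];
    gc_ = goal[1];
  }
  void successors(const std::string& s, std::vector<Succ>& out) {
    out.clear();
    int r, c;
    parse_cell(s, r, c);
    static const int DR4[4] = {-1, 1, 0, 0};
    static const int DC4[4] = {0, 0, -1, 1};
    static const int DR8[4] = {-1, -1, 1, 1};
    static const int DC8[4] = {-1, 1, -1, 1};
    const double SQ2 = std::sqrt(2.0);
    for (int k = 0; k < 4; ++k) {
      int nr = r + DR4[k], nc = c + DC4[k];
      if (nr < 0 || nr >= H_ || nc < 0 || nc >= W_ || blocked_[nr * W_ + nc])
        continue;
      out.push_back({cell_str(nr, nc), 1.0});
    }
    if (conn_ == 8) {
      for (int k = 0; k < 4; ++k) {
        int nr = r + DR8[k], nc = c + DC8[k];
        if (nr < 0 || nr >= H_ || nc < 0 || nc >= W_ || blocked_[nr * W_ + nc])
          continue;
        if (blocked_[r * W_ + nc] || blocked_[nr * W_ + c]) continue;
        out.push_back({cell_str(nr, nc), SQ2});
      }
    }
  }
  double heuristic(const std::string& s) {
    int r, c;
    parse_cell(s, r, c);
    double dr = r - gr_, dc = c - gc_;
    return std::sqrt(dr * dr + dc * dc);
  }
  bool is_goal(const std::string& s) {
    int r, c;
    parse_cell(s, r, c);
    return r == gr_ && c == gc_;
  }
};

// Arbitrary state space supplied from R: states are opaque character tokens,
// successors(state) returns data.frame(state = character, cost = numeric).
class CustomDomain : public Domain {
  Function succ_, h_, goal_;

 public:
  CustomDomain(Function s, Function h, Function g) : succ_(s), h_(h), goal_(g) {}
  void successors(const std::string& s, std::vector<Succ>& out) {
    out.clear();
    DataFrame df = succ_(s);
    CharacterVector st = df["state"];
    NumericVector co = df["cost"];
    for (R_xlen_t i = 0; i < st.size(); ++i)
      out.push_back({std::string(st[i]), co[i]});
  }
  double heuristic(const std::string& s) { return as<double>(h_(s)); }
  bool is_goal(const std::string& s) { return as<bool>(goal_(s)); }
};

// ---------------------------------------------------------------------------
// Best-first engine: weighted A* (f = (1-w) g + w h) with dynamic re-weighting
// and FOCAL (A*eps) node selection.  Tie-breaking is fixed: smaller f, then
// larger g, then first-in insertion order.  Closed states are re-opened when
// rediscovered with a strictly lower g, including after a weight change; on a
// weight change the whole OPEN list is re-evaluated and the priority queue
// rebuilt.
// ---------------------------------------------------------------------------

struct NodeRec {
  std::string state;
  double g, h, sec;
  int parent;
  long order;
  bool open, closed, in_ov, ever_expanded;
};

struct HeapEnt {
  double f, g;
  long order;
  int id;
};

struct HeapCmp {
  bool operator()(const HeapEnt& a, const HeapEnt& b) const {
    if (a.f != b.f) return a.f > b.f;
    if (a.g != b.g) return a.g < b.g;
    return a.order > b.order;
  }
};

typedef std::priority_queue<HeapEnt, std::vector<HeapEnt>, HeapCmp> Heap;

// [[Rcpp::export]]
List cpp_search(List problem, List control) {
  std::string kind = as<std::string>(problem["kind"]);
  std::unique_ptr<Domain> dom;
  std::string init;
  if (kind == "puzzle") {
    dom.reset(new PuzzleDomain(as<std::string>(problem["goal"])));
    init = as<std::string>(problem["start"]);
    tiles_from_string(init);  // validate
  } else if (kind == "grid") {
    dom.reset(new GridDomain(as<LogicalMatrix>(problem["blocked"]),
                             as<IntegerVector>(problem["goal"]),
                             as<int>(problem["connectivity"])));
    IntegerVector st = problem["start"];
    init = cell_str(st[0], st[1]);
  } else if (kind == "custom") {
    dom.reset(new CustomDomain(problem["successors"], problem["heuristic"],
                               problem["goal_test"]));
    init = as<std::string>(problem["initial"]);
  } else {
    stop("unknown problem kind");
  }

  std::string mode = as<std::string>(control["mode"]);  // "weighted" | "focal"
  bool focal = (mode == "focal");
  double w0 = as<double>(control["initial_omega"]);
  NumericVector tfrac = control["trigger_fraction"];
  NumericVector tw = control["trigger_weight"];
  bool monotone = as<bool>(control["monotone"]);
  double reference = as<double>(control["reference"]);
  double eps = as<double>(control["epsilon"]);
  std::string sec_mode = as<std::string>(control["secondary"]);
  RObject sec_obj = control["secondary_fn"];
  bool sec_custom = (sec_mode == "custom");
  double budget = as<double>(control["node_budget"]);
  bool keep_trace = as<bool>(control["keep_trace"]);

  // Schedule: the weight in effect once `expanded` nodes have been expanded
  // is the latest trigger whose fraction of the reference exploration has
  // been reached (running maximum when the monotone flag is set).
  const int ntrig = tfrac.size();
  double cur_w = w0;
  {
    for (int i = 0; i < ntrig; ++i)
      if (0.0 + 1e-9 >= tfrac[i] * reference)
        cur_w = monotone ? std::max(cur_w, tw[i]) : tw[i];
  }

  std::vector<NodeRec> nodes;
  nodes.reserve(1024);
  std::unordered_map<std::string, int> index;
  long order_counter = 0;
  Heap heap;
  std::vector<int> open_vec;  // FOCAL only
  int open_count = 0;

  const double fw = focal ? 0.5 : cur_w;  // FOCAL uses the unweighted blend
  (void)fw;

  // local helpers -----------------------------------------------------------
  struct Helpers {
    std::vector<NodeRec>& nodes;
    double fval(int id, double w) const {
      return (1.0 - w) * nodes[id].g + w * nodes[id].h;
    }
  } H{nodes};

  std::vector<Succ> succs;

  // create node (never call while holding a NodeRec reference: push_back may
  // reallocate)
  // returns id
  // sec value cached at creation (depends only on the state)
  // ------------------------------------------------------------------------
  // main loop state
  double expanded = 0;
  int goal_id = -1;
  bool exhausted = false;
  double max_w = cur_w;

  std::vector<int> tr_idx, tr_open;
  std::vector<std::string> tr_state;
  std::vector<double> tr_g, tr_h, tr_f, tr_w, h_seq;

  // lambda: make node
  int sid;
  {
    double h0 = dom->heuristic(init);
    if (h0 < 0) stop("heuristic returned a negative value");
    double sec = 0.0;
    if (focal) {
      if (sec_mode == "h")
        sec = h0;
      else if (sec_custom)
        sec = as<double>(Function(sec_obj)(init));
    }
    nodes.push_back(NodeRec{init, 0.0, h0, sec, -1, order_counter++, true,
                            false, false, false});
    sid = 0;
    index[init] = sid;
  }
  if (focal) {
    open_vec.push_back(sid);
    nodes[sid].in_ov = true;
  } else {
    heap.push(HeapEnt{H.fval(sid, cur_w), 0.0, nodes[sid].order, sid});
  }
  open_count = 1;

  while (true) {
    if (!focal && ntrig > 0) {
      double w_new = w0;
      for (int i = 0; i < ntrig; ++i)
        if (expanded + 1e-9 >= tfrac[i] * reference)
          w_new = monotone ? std::max(w_new, tw[i]) : tw[i];
      if (monotone) w_new = std::max(w_new, w0);
      if (w_new != cur_w) {
        cur_w = w_new;
        Heap empty;
        heap.swap(empty);
        for (int id = 0; id < static_cast<int>(nodes.size()); ++id)
          if (nodes[id].open)
            heap.push(HeapEnt{H.fval(id, cur_w), nodes[id].g, nodes[id].order,
                              id});
      }
      if (cur_w > max_w) max_w = cur_w;
    }

    int id = -1;
    if (!focal) {
      while (!heap.empty()) {
        HeapEnt e = heap.top();
        if (!nodes[e.id].open || e.g != nodes[e.id].g) {
          heap.pop();
          continue;
        }
        id = e.id;
        heap.pop();
        break;
      }
      if (id < 0) break;  // OPEN exhausted, no solution
    } else {
      // pass 1: compact invalid entries, find min f over OPEN
      double fmin = R_PosInf;
      for (size_t k = 0; k < open_vec.size();) {
        int nid = open_vec[k];
        if (!nodes[nid].open) {
          nodes[nid].in_ov = false;
          open_vec[k] = open_vec.back();
          open_vec.pop_back();
          continue;
        }
        double f = H.fval(nid, 0.5);
        if (f < fmin) fmin = f;
        ++k;
      }
      if (open_vec.empty()) break;
      // pass 2: FOCAL = {n : f(n) <= (1+eps) fmin}; pick min secondary,
      // ties by smaller f, then larger g, then insertion order
      double thr = (1.0 + eps) * fmin + 1e-9;
      int best = -1;
      double best_f = 0;
      for (size_t k = 0; k < open_vec.size(); ++k) {
        int nid = open_vec[k];
        double f = H.fval(nid, 0.5);
        if (f > thr) continue;
        if (best < 0) {
          best = nid;
          best_f = f;
          continue;
        }
        const NodeRec& a = nodes[nid];
        const NodeRec& b = nodes[best];
        bool better = false;
        if (a.sec != b.sec)
          better = a.sec < b.sec;
        else if (f != best_f)
          better = f < best_f;
        else if (a.g != b.g)
          better = a.g > b.g;
        else
          better = a.order < b.order;
        if (better) {
          best = nid;
          best_f = f;
        }
      }
      id = best;
      if (id < 0) break;
    }

    // expand ---------------------------------------------------------------
    nodes[id].open = false;
    nodes[id].closed = true;
    nodes[id].ever_expanded = true;
    open_count--;
    expanded += 1;
    double g0 = nodes[id].g;
    double h0 = nodes[id].h;
    std::string s0 = nodes[id].state;
    double w_rec = focal ? 0.5 : cur_w;
    h_seq.push_back(h0);

    if (dom->is_goal(s0)) {
      goal_id = id;
      if (keep_trace) {
        tr_idx.push_back(static_cast<int>(expanded));
        tr_state.push_back(s0);
        tr_g.push_back(g0);
        tr_h.push_back(h0);
        tr_f.push_back((1.0 - w_rec) * g0 + w_rec * h0);
        tr_w.push_back(w_rec);
        tr_open.push_back(open_count);
      }
      break;
    }

    dom->successors(s0, succs);
    for (size_t si = 0; si < succs.size(); ++si) {
      const Succ& sc = succs[si];
      if (sc.cost <= 0) stop("edge costs must be strictly positive");
      double g2 = g0 + sc.cost;
      std::unordered_map<std::string, int>::iterator it = index.find(sc.s);
      if (it == index.end()) {
        double h2 = dom->heuristic(sc.s);
        if (h2 < 0) stop("heuristic returned a negative value");
        double sec = 0.0;
        if (focal) {
          if (sec_mode == "h")
            sec = h2;
          else if (sec_custom)
            sec = as<double>(Function(sec_obj)(sc.s));
        }
        nodes.push_back(NodeRec{sc.s, g2, h2, sec, id, order_counter++, true,
                                false, false, false});
        int nid = static_cast<int>(nodes.size()) - 1;
        index[sc.s] = nid;
        open_count++;
        if (focal) {
          open_vec.push_back(nid);
          nodes[nid].in_ov = true;
        } else {
          heap.push(HeapEnt{H.fval(nid, cur_w), g2, nodes[nid].order, nid});
        }
      } else {
        int nid = it->second;
        if (g2 < nodes[nid].g - 1e-12) {
          nodes[nid].g = g2;
          nodes[nid].parent = id;
          if (nodes[nid].closed) {  // re-open
            nodes[nid].closed = false;
            nodes[nid].open = true;
            open_count++;
            if (focal) {
              if (!nodes[nid].in_ov) {
                open_vec.push_back(nid);
                nodes[nid].in_ov = true;
              }
            } else {
              heap.push(HeapEnt{H.fval(nid, cur_w), g2, nodes[nid].order, nid});
            }
          } else if (nodes[nid].open && !focal) {
            heap.push(HeapEnt{H.fval(nid, cur_w), g2, nodes[nid].order, nid});
          }
        }
      }
    }

    if (keep_trace) {
      tr_idx.push_back(static_cast<int>(expanded));
      tr_state.push_back(s0);
      tr_g.push_back(g0);
      tr_h.push_back(h0);
      tr_f.push_back((1.0 - w_rec) * g0 + w_rec * h0);
      tr_w.push_back(w_rec);
      tr_open.push_back(open_count);
    }

    if (expanded >= budget) {
      exhausted = true;
      break;
    }
  }

  bool found = goal_id >= 0;
  RObject path(R_NilValue);  // RObject keeps the SEXPs protected until return
  double cost = NA_REAL;
  if (found) {
    std::vector<std::string> rev;
    for (int id = goal_id; id >= 0; id = nodes[id].parent)
      rev.push_back(nodes[id].state);
    std::reverse(rev.begin(), rev.end());
    path = wrap(rev);
    cost = nodes[goal_id].g;
  }

  RObject trace(R_NilValue);
  if (keep_trace) {
    trace = DataFrame::create(
        _["expansion"] = tr_idx, _["state"] = tr_state, _["g"] = tr_g,
        _["h"] = tr_h, _["f"] = tr_f, _["omega"] = tr_w,
        _["open_size"] = tr_open, _["stringsAsFactors"] = false);
  }

  // distinct states expanded at least once (re-expansions of re-opened
  // states excluded); for consistent heuristics this equals nodes_expanded
  double distinct = 0;
  for (size_t i = 0; i < nodes.size(); ++i)
    if (nodes[i].ever_expanded) distinct += 1;

  return List::create(
      _["nodes_expanded"] = expanded, _["nodes_explored"] = distinct,
      _["found"] = found,
      _["solution_path"] = path, _["solution_cost"] = cost,
      _["max_omega"] = max_w, _["budget_exhausted"] = exhausted,
      _["h_sequence"] = NumericVector(h_seq.begin(), h_seq.end()),
      _["expansions"] = trace);
}
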