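#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Floyd-Warshall on a dense length matrix held in a flat vector.
// d must be initialised with 0 on the diagonal, edge lengths where an edge
// exists and R_PosInf elsewhere.
static void fw_inplace(std::vector<double>& d, const int n) {
    for (int k = 0; k < n; ++k) {
        const double* dk = &d[(size_t)k * n];
        for (int i = 0; i < n; ++i) {
            const double dik = d[(size_t)i * n + k];
            if (dik == R_PosInf) continue;
            double* di = &d[(size_t)i * n];
            for (int j = 0; j < n; ++j) {
                const double alt = dik + dk[j];
                if (alt < di[j]) di[j] = alt;
            }
        }
    }
}

// Mean nodal global efficiency via Dijkstra from every source on an
// adjacency-list representation; faster than Floyd-Warshall on the sparse
// networks that low costs produce. Lengths are 1/w.
#include <queue>
static double dijkstra_mean_eglob(const std::vector<std::vector<std::pair<int, double> > >& adj,
                                  const int n) {
    if (n < 2) return 0.0;
    double total = 0.0;
    std::vector<double> dist(n);
    typedef std::pair<double, int> QE;
    for (int s = 0; s < n; ++s) {
        std::fill(dist.begin(), dist.end(), R_PosInf);
        dist[s] = 0.0;
        std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
        pq.push(QE(0.0, s));
        while (!pq.empty()) {
            const QE top = pq.top(); pq.pop();
            if (top.first > dist[top.second]) continue;
            const int u = top.second;
            for (size_t e = 0; e < adj[u].size(); ++e) {
                const int v = adj[u][e].first;
                const double alt = top.first + adj[u][e].second;
                if (alt < dist[v]) {
                    dist[v] = alt;
                    pq.push(QE(alt, v));
                }
            }
        }
        double sum = 0.0;
        for (int j = 0; j < n; ++j)
            if (j != s && dist[j] < R_PosInf && dist[j] > 0.0)
                sum += 1.0 / dist[j];
        total += sum / (double)(n - 1);
    }
    return total / (double)n;
}

// All-pairs shortest weighted path lengths with edge length 1/W_ij
// (functional distance). Unreachable pairs are +Inf, diagonal 0.
// [[Rcpp::export]]
NumericMatrix cpp_shortest_paths(const NumericMatrix& W) {
    const int n = W.nrow();
    std::vector<double> d((size_t)n * n);
    for (int i = 0; i < n; ++i)
        for (int j = 0; j < n; ++j)
            d[(size_t)i * n + j] =
                (i == j) ? 0.0 : (W(i, j) > 0.0 ? 1.0 / W(i, j) : R_PosInf);
    fw_inplace(d, n);
    NumericMatrix out(n, n);
    for (int i = 0; i < n; ++i)
        for (int j = 0; j < n; ++j) out(i, j) = d[(size_t)i * n + j];
    return out;
}

// Nodal global efficiency, nodal local efficiency and degrees in one pass.
// Global: E_glob(i) = (1/(N-1)) * sum_{j != i} 1/L_ij, 1/Inf := 0.
// Local: shortest paths are confined to the subgraph induced by the direct
// neighbours of i; E_loc(i) = (1/(k_i(k_i-1))) * sum_{j != h} 1/L'_jh,
// and E_loc(i) = 0 when k_i < 2.
// [[Rcpp::export]]
List cpp_efficiency(const NumericMatrix& W) {
    const int n = W.nrow();
    NumericVector eglob(n), eloc(n);
    IntegerVector degree(n);

    std::vector<double> d((size_t)n * n);
    for (int i = 0; i < n; ++i)
        for (int j = 0; j < n; ++j)
            d[(size_t)i * n + j] =
                (i == j) ? 0.0 : (W(i, j) > 0.0 ? 1.0 / W(i, j) : R_PosInf);
    fw_inplace(d, n);

    for (int i = 0; i < n; ++i) {
        double s = 0.0;
        for (int j = 0; j < n; ++j) {
            if (j == i) continue;
            const double L = d[(size_t)i * n + j];
            if (L < R_PosInf && L > 0.0) s += 1.0 / L;
        }
        eglob[i] = (n > 1) ? s / (double)(n - 1) : 0.0;
    }

    std::vector<int> nbr;
    std::vector<double> sub;
    for (int i = 0; i < n; ++i) {
        nbr.clear();
        for (int j = 0; j < n; ++j)
            if (W(i, j) > 0.0) nbr.push_back(j);
        const int k = (int)nbr.size();
        degree[i] = k;
        if (k < 2) { eloc[i] = 0.0; continue; }
        sub.assign((size_t)k * k, R_PosInf);
        for (int a = 0; a < k; ++a) {
            sub[(size_t)a * k + a] = 0.0;
            for (int b = a + 1; b < k; ++b) {
                const double w = W(nbr[a], nbr[b]);
                if (w > 0.0) {
                    sub[(size_t)a * k + b] = 1.0 / w;
                    sub[(size_t)b * k + a] = 1.0 / w;
                }
            }
        }
        fw_inplace(sub, k);
        double s = 0.0;
        for (int a = 0; a < k; ++a)
            for (int b = 0; b < k; ++b) {
                if (a == b) continue;
                const double L = sub[(size_t)a * k + b];
                if (L < R_PosInf && L > 0.0) s += 1.0 / L;
            }
        eloc[i] = s / ((double)k * (double)(k - 1));
    }

    return List::create(_["eglob"] = eglob, _["eloc"] = eloc,
                        _["degree"] = degree);
}

// Network-average local efficiency only (used for surrogate ensembles,
// where nodal values are not needed).
static double mean_eloc(const NumericMatrix& W) {
    const int n = W.nrow();
    std::vector<int> nbr;
    std::vector<double> sub;
    double total = 0.0;
    for (int i = 0; i < n; ++i) {
        nbr.clear();
        for (int j = 0; j < n; ++j)
            if (W(i, j) > 0.0) nbr.push_back(j);
        const int k = (int)nbr.size();
        if (k < 2) continue;
        sub.assign((size_t)k * k, R_PosInf);
        for (int a = 0; a < k; ++a) {
            sub[(size_t)a * k + a] = 0.0;
            for (int b = a + 1; b < k; ++b) {
                const double w = W(nbr[a], nbr[b]);
                if (w > 0.0) {
                    sub[(size_t)a * k + b] = 1.0 / w;
                    sub[(size_t)b * k + a] = 1.0 / w;
                }
            }
        }
        fw_inplace(sub, k);
        double s = 0.0;
        for (int a = 0; a < k; ++a)
            for (int b = 0; b < k; ++b) {
                if (a == b) continue;
                const double L = sub[(size_t)a * k + b];
                if (L < R_PosInf && L > 0.0) s += 1.0 / L;
            }
        total += s / ((double)k * (double)(k - 1));
    }
    return total / (double)n;
}

// Degree-preserving double-edge swaps (Maslov-Sneppen). `edges` is an m x 2
// 1-based endpoint matrix; each row keeps its position so edge attributes
// (weights) stored per row travel with the rewired edge. Swaps that would
// create a self-loop or a duplicate edge are rejected. Uses R's RNG, so
// results are reproducible under set.seed().
// [[Rcpp::export]]
List cpp_rewire(IntegerMatrix edges, const int n_nodes,
                const int n_attempts) {
    const int m = edges.nrow();
    IntegerMatrix out = clone(edges);
    std::vector<char> adj((size_t)n_nodes * n_nodes, 0);
    for (int e = 0; e < m; ++e) {
        const int a = out(e, 0) - 1, b = out(e, 1) - 1;
        adj[(size_t)a * n_nodes + b] = 1;
        adj[(size_t)b * n_nodes + a] = 1;
    }
    int n_swaps = 0;
    for (int t = 0; t < n_attempts; ++t) {
        const int e1 = (int)(unif_rand() * m);
        const int e2 = (int)(unif_rand() * m);
        if (e1 == e2) continue;
        int a = out(e1, 0) - 1, b = out(e1, 1) - 1;
        int c = out(e2, 0) - 1, d = out(e2, 1) - 1;
        if (unif_rand() < 0.5) std::swap(c, d);
        // proposed replacement: (a,b),(c,d) -> (a,d),(c,b)
        if (a == d || c == b || a == c || b == d) continue;
        if (adj[(size_t)a * n_nodes + d] || adj[(size_t)c * n_nodes + b])
            continue;
        adj[(size_t)a * n_nodes + b] = adj[(size_t)b * n_nodes + a] = 0;
        adj[(size_t)c * n_nodes + d] = adj[(size_t)d * n_nodes + c] = 0;
        adj[(size_t)a * n_nodes + d] = adj[(size_t)d * n_nodes + a] = 1;
        adj[(size_t)c * n_nodes + b] = adj[(size_t)b * n_nodes + c] = 1;
        out(e1, 0) = a + 1; out(e1, 1) = d + 1;
        out(e2, 0) = c + 1; out(e2, 1) = b + 1;
        ++n_swaps;
    }
    return List::create(_["edges"] = out, _["n_swaps"] = n_swaps);
}

// Batch surrogate ensemble: rewires the edge list n_surr times (fresh copy
// each time) and returns the mean network-average global and local
// efficiency across the ensemble. Equivalent to repeated cpp_rewire +
// cpp_efficiency but without per-surrogate R overhead.
// [[Rcpp::export]]
NumericVector cpp_surrogate_means(const NumericMatrix& W, const int n_surr,
                                  const int n_attempts) {
    const int n = W.nrow();
    std::vector<int> ea, eb;
    std::vector<double> ew;
    for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j)
            if (W(i, j) > 0.0) {
                ea.push_back(i); eb.push_back(j); ew.push_back(W(i, j));
            }
    const int m = (int)ea.size();
    double sum_eg = 0.0, sum_el = 0.0;
    std::vector<int> a(m), b(m);
    std::vector<char> adj((size_t)n * n);
    NumericMatrix Ws(n, n);
    std::vector<std::vector<std::pair<int, double> > > alist(n);
    for (int i = 0; i < n; ++i) alist[i].reserve(2 * m / n + 4);
    for (int s = 0; s < n_surr; ++s) {
        a = ea; b = eb;
        std::fill(adj.begin(), adj.end(), 0);
        for (int e = 0; e < m; ++e) {
            adj[(size_t)a[e] * n + b[e]] = 1;
            adj[(size_t)b[e] * n + a[e]] = 1;
        }
        for (int t = 0; t < n_attempts; ++t) {
            const int e1 = (int)(unif_rand() * m);
            const int e2 = (int)(unif_rand() * m);
            if (e1 == e2) continue;
            int p = a[e1], q = b[e1], r = a[e2], u = b[e2];
            if (unif_rand() < 0.5) std::swap(r, u);
            if (p == u || r == q || p == r || q == u) continue;
            if (adj[(size_t)p * n + u] || adj[(size_t)r * n + q]) continue;
            adj[(size_t)p * n + q] = adj[(size_t)q * n + p] = 0;
            adj[(size_t)r * n + u] = adj[(size_t)u * n + r] = 0;
            adj[(size_t)p * n + u] = adj[(size_t)u * n + p] = 1;
            adj[(size_t)r * n + q] = adj[(size_t)q * n + r] = 1;
            a[e1] = p; b[e1] = u;
            a[e2] = r; b[e2] = q;
        }
        std::fill(Ws.begin(), Ws.end(), 0.0);
        for (int e = 0; e < m; ++e) {
            Ws(a[e], b[e]) = ew[e];
            Ws(b[e], a[e]) = ew[e];
        }
        const double density = (double)(2 * m) / ((double)n * (n - 1));
        if (density <= 0.2) {
            // sparse: Dijkstra from every source beats Floyd-Warshall
            for (int i = 0; i < n; ++i) alist[i].clear();
            for (int e = 0; e < m; ++e) {
                alist[a[e]].push_back(std::make_pair(b[e], 1.0 / ew[e]));
                alist[b[e]].push_back(std::make_pair(a[e], 1.0 / ew[e]));
            }
            sum_eg += dijkstra_mean_eglob(alist, n);
        } else {
            std::vector<double> d((size_t)n * n);
            for (int i = 0; i < n; ++i)
                for (int j = 0; j < n; ++j)
                    d[(size_t)i * n + j] = (i == j) ? 0.0 :
                        (Ws(i, j) > 0.0 ? 1.0 / Ws(i, j) : R_PosInf);
            fw_inplace(d, n);
            double total = 0.0;
            for (int i = 0; i < n; ++i) {
                double s2 = 0.0;
                for (int j = 0; j < n; ++j) {
                    if (j == i) continue;
                    const double L = d[(size_t)i * n + j];
                    if (L < R_PosInf && L > 0.0) s2 += 1.0 / L;
                }
                total += s2 / (double)(n - 1);
            }
            sum_eg += total / (double)n;
        }
        sum_el += mean_eloc(Ws);
    }
    return NumericVector::create(sum_eg / n_surr, sum_el / n_surr);
}
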