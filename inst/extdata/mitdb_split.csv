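record,set
101,DS1
106,DS1
108,DS1
109,DS1
112,DS1
114,DS1
115,DS1
116,DS1
118,DS1
119,DS1
122,DS1
124,DS1
201,DS1
203,DS1
205,DS1
207,DS1
208,DS1
209,DS1
215,DS1
220,DS1
223,DS1
230,DS1
100,DS2
103,DS2
105,DS2
111,DS2
113,DS2
117,DS2
121,DS2
123,DS2
200,DS2
202,DS2
210,DS2
212,DS2
213,DS2
214,DS2
219,DS2
221,DS2
222,DS2
228,DS2
231,DS2
232,DS2
233,DS2
234,DS2
102,excluded
104,excluded
107,excluded
217,excluded
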