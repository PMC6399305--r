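group_id,task_id,role,event_name,content,timestamp
G0001,T1,A,task start,,2024-03-01T09:00:01
G0001,T1,A,controlA,status: on,2024-03-01T09:00:02
G0001,T1,A,chat,let me try control A first,2024-03-01T09:00:03
G0001,T1,B,chat,ok I will watch the display,2024-03-01T09:00:04
G0001,T1,A,chat,temperature went up,2024-03-01T09:00:05
G0001,T1,B,chat,try the other slider,2024-03-01T09:00:06
G0001,T1,A,controlB,status: 2,2024-03-01T09:00:07
G0001,T1,A,apply,A,2024-03-01T09:00:08
G0001,T1,B,controlC,status: on,2024-03-01T09:00:09
G0001,T1,B,controlD,status: 1,2024-03-01T09:00:10
G0001,T1,B,apply,B,2024-03-01T09:00:11
G0001,T1,B,task result,success,2024-03-01T09:00:12
G0001,T1,B,task end,,2024-03-01T09:00:13
G0002,T1,A,task start,,2024-03-01T09:05:01
G0002,T1,A,chat,what do you see,2024-03-01T09:05:02
G0002,T1,B,chat,two sliders C and D,2024-03-01T09:05:03
G0002,T1,B,controlC,status: on,2024-03-01T09:05:04
G0002,T1,A,controlA,status: off,2024-03-01T09:05:05
G0002,T1,B,task result,failure,2024-03-01T09:05:06
G0002,T1,B,task end,,2024-03-01T09:05:07
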